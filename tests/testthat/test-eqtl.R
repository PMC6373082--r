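test_that("genotype encoding maps WT/HET/KO to 1/0.5/0", {
  expect_equal(encodeGenotypes(c("WT", "HET", "KO")), c(1, 0.5, 0))
  expect_equal(encodeGenotypes(c("KO", "KO")), c(0, 0))
  expect_error(encodeGenotypes(character()), "non-empty")
  expect_error(encodeGenotypes(c("WT", "weird")), "unknown genotype")
})

test_that("per-gene OLS matches the hand-worked example and lm()", {
  x <- c(1, 1, 0.5, 0.5, 0, 0)
  y <- c(10, 9, 6, 5, 2, 1)
  res <- screenEqtl(rbind(g1 = y), x)
  expect_equal(res$slope, 8)
  expect_equal(res$p_value, 2 * pt(-8 / sqrt(1.5 / 4), df = 4),
               tolerance = 1e-12)
  expect_lt(res$p_value, 3e-4)
  expect_true(res$selected)

  # generic least-squares oracle on random genes
  set.seed(101)
  m <- matrix(rnorm(5 * 9, 10, 2), 5, 9)
  g <- rep(c("WT", "HET", "KO"), each = 3)
  res2 <- screenEqtl(m, g)
  for (i in 1:5) {
    fit <- summary(lm(m[i, ] ~ encodeGenotypes(g)))
    expect_equal(res2$slope[i], unname(coef(fit)[2, 1]), tolerance = 1e-9)
    expect_equal(res2$p_value[i], unname(coef(fit)[2, 4]),
                 tolerance = 1e-9)
  }
})

test_that("flat or degenerate expression is handled explicitly", {
  x <- c("WT", "WT", "HET", "KO", "KO")
  flat <- screenEqtl(rbind(g = rep(3, 5)), x)
  expect_equal(flat$slope, 0)
  expect_false(flat$selected)

  # perfect linear fit: smallest representable p, flagged
  perfect <- screenEqtl(rbind(g = encodeGenotypes(x) * 4 + 1), x)
  expect_true(perfect$perfect_fit)
  expect_equal(perfect$p_value, .Machine$double.xmin)

  expect_error(screenEqtl(rbind(g = 1:3), c("KO", "KO", "KO")),
               "one genotype")
  expect_error(screenEqtl(rbind(g = 1:2), c("WT", "KO")), "3 samples")
})

test_that("slope and p are invariant to sample order and code scaling", {
  set.seed(111)
  y <- rnorm(9, 5)
  g <- rep(c(1, 0.5, 0), each = 3)
  a <- screenEqtl(rbind(y = y), g)
  perm <- sample(9)
  b <- screenEqtl(rbind(y = y[perm]), g[perm])
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  sc <- screenEqtl(rbind(y = y), 2 * g)
  expect_equal(sc$slope, a$slope / 2, tolerance = 1e-12)
  expect_equal(sc$p_value, a$p_value, tolerance = 1e-12)
})

test_that("two-group (WT/KO only) screens are allowed and flagged", {
  set.seed(121)
  m <- matrix(rnorm(3 * 6, 8), 3, 6)
  res <- screenEqtl(m, c("WT", "WT", "WT", "KO", "KO", "KO"))
  expect_true(attr(res, "twoGroup"))
  expect_equal(nrow(res), 3L)
})

test_that("candidate selection requires significance in both conditions", {
  ctrl <- data.frame(gene = c("a", "b", "c"), p_value = c(0.001, 0.2, 0.01),
                     selected = c(TRUE, FALSE, TRUE))
  pert <- data.frame(gene = c("a", "b", "c"), p_value = c(0.04, 0.01, 0.2),
                     selected = c(TRUE, TRUE, FALSE))
  expect_equal(selectCandidates(ctrl, pert), "a")
  none <- pert; none$selected <- FALSE
  expect_equal(selectCandidates(ctrl, none), character())
  # order-stable by ascending control p
  pert2 <- pert; pert2$selected <- TRUE
  expect_equal(selectCandidates(ctrl, pert2), c("a", "c"))
})

test_that("null simulation holds the type-I error near alpha", {
  tab <- simulateCountTable(rep(0, 400), rep(c("WT", "HET", "KO"), each = 3),
                            sigma = 1, seed = 1001)
  res <- screenEqtl(tab$counts, tab$genotypes)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(res$selected) - 0.05), 3 * se + 1e-12)
})

test_that("simulated slopes are recovered within their standard errors", {
  slopes <- runif(60, -6, 6)
  g <- rep(c("WT", "HET", "KO"), each = 3)
  tab <- simulateCountTable(slopes, g, intercepts = 30, sigma = 1,
                            seed = 2002)
  res <- screenEqtl(tab$counts, tab$genotypes)
  codes <- encodeGenotypes(g)
  seBeta <- 1 / sqrt(sum((codes - mean(codes))^2))  # sigma = 1
  hit <- mean(abs(res$slope - slopes) <= 2 * seBeta)
  expect_gte(hit, 0.93)

  # noiseless limit
  exact <- simulateCountTable(c(10, -2), g, sigma = 1e-9, seed = 3003)
  fits <- screenEqtl(exact$counts, exact$genotypes)
  expect_equal(fits$slope, c(10, -2), tolerance = 1e-6)
})

test_that("screen sensitivity matches noncentral-t power for the design", {
  # 9 samples (3/3/3), effect/sigma = 4: power from the noncentral t
  g <- rep(c("WT", "HET", "KO"), each = 3)
  codes <- encodeGenotypes(g)
  sxx <- sum((codes - mean(codes))^2)
  ncp <- 4 * sqrt(sxx)
  crit <- qt(0.975, df = 7)
  power <- pt(-crit, 7, ncp) + 1 - pt(crit, 7, ncp)
  expect_gte(power, 0.9)

  slopes <- rep(c(4, 0), c(40, 160))  # 20% non-null at effect/sigma = 4
  tab <- simulateCountTable(slopes, g, sigma = 1, seed = 4004)
  res <- screenEqtl(tab$counts, tab$genotypes)
  sens <- mean(res$selected[slopes != 0])
  expect_gte(sens, 0.9)
  expect_lt(abs(sens - power), 3 * sqrt(power * (1 - power) / 40) + 0.02)
})

test_that("count tables and sample sheets round-trip from TSV", {
  g <- c("WT", "WT", "KO", "KO")
  tab <- simulateCountTable(c(5, 0), g, seed = 5005)
  cf <- tempfile(fileext = ".tsv"); sf <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(tab$counts), tab$counts,
                         check.names = FALSE),
              cf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(tab$counts), genotype = g,
                         condition = "control"),
              sf, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- readCountTable(cf, sf)
  expect_equal(unname(rt$counts), unname(tab$counts), tolerance = 1e-12)
  expect_equal(rt$samples$genotype, g)
  bad <- tempfile(); writeLines("sample_id\tstuff\ns01\tx", bad)
  expect_error(readCountTable(cf, bad), "genotype")
})
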