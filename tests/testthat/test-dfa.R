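make_pairs <- function(day, night) {
  # rows: one pair with given day/night sample vectors
  M <- rbind(day, night)
  rownames(M) <- c("p1_Day", "p1_Night")
  list(samples = structure(list(reaction_ids = rownames(M), samples = M,
                                seed = 0), class = "sample_matrix"),
       phase_map = structure(list(reactions = list(
         day = c(p1 = "p1_Day"), night = c(p1 = "p1_Night"))),
         class = "phase_map"))
}

test_that("identical day and night rows are never called different", {
  const <- make_pairs(rep(2, 50), rep(2, 50))
  d1 <- differential_reactions(const$samples, const$phase_map)
  expect_equal(d1$p_value, 1)
  expect_false(d1$significant)

  x <- sin(1:50)
  same <- make_pairs(x, x)
  d2 <- differential_reactions(same$samples, same$phase_map)
  expect_gt(d2$p_value, 0.9)
  expect_false(d2$significant)
})

test_that("fully separated rows reach the closed-form Mann-Whitney floor", {
  sep <- make_pairs(rep(10, 100), rep(0, 100))
  d <- differential_reactions(sep$samples, sep$phase_map)
  expect_equal(d$p_value, mw_p_separated(100, 100), tolerance = 1e-12)
  expect_true(d$significant)
  expect_equal(d$statistic, 100 * 100)
})

test_that("BH correction keeps q above p and drives significance", {
  np <- make_null_sample_pairs(n_pairs = 40, n_samples = 30, seed = 5,
                               effect_size = 0)
  d <- differential_reactions(np$samples, np$phase_map)
  expect_true(all(d$q_value >= d$p_value - 1e-12))
  expect_identical(d$significant, d$q_value < 0.05)
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
})

test_that("missing phase rows are reported by id", {
  np <- make_null_sample_pairs(5, 10, seed = 1)
  pm <- np$phase_map
  pm$reactions$day[["extra"]] <- "extra_Day"
  pm$reactions$night[["extra"]] <- "extra_Night"
  expect_error(differential_reactions(np$samples, pm), "extra_Day")
})

test_that("the KS alternative is available behind the method flag", {
  np <- make_null_sample_pairs(10, 40, seed = 9, effect_size = 3)
  d <- differential_reactions(np$samples, np$phase_map, method = "ks")
  expect_true(all(d$significant))
})

test_that("null calibration: BH-significant fraction stays near alpha", {
  np <- make_null_sample_pairs(n_pairs = 200, n_samples = 100, seed = 17,
                               effect_size = 0)
  d <- differential_reactions(np$samples, np$phase_map, alpha = 0.05)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(d$significant), 0.05 + 3 * se)
})

test_that("a five-sigma shift makes every pair significant", {
  np <- make_null_sample_pairs(n_pairs = 50, n_samples = 100, seed = 23,
                               effect_size = 5)
  d <- differential_reactions(np$samples, np$phase_map)
  expect_true(all(d$significant))
})

test_that("tiny sample sizes still return valid p-values", {
  np <- make_null_sample_pairs(n_pairs = 5, n_samples = 2, seed = 2)
  d <- differential_reactions(np$samples, np$phase_map)
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  # spec-level worked example: N=20, K=5, n=10, k=5
  expect_equal(hyper_tail_oracle(20, 5, 10, 5), 3003 / 184756)
  expect_equal(stats::phyper(4, 5, 15, 10, lower.tail = FALSE),
               3003 / 184756, tolerance = 1e-12)
  # a modest grid here; the full N <= 25 sweep runs in the acceptance suite
  for (N in c(6, 11, 17)) {
    for (K in c(1, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N)) {
        for (k in 0:min(K, n)) {
          expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       hyper_tail_oracle(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("pathway enrichment counts pairs and sorts by p-value", {
  fx <- make_toy_plant_gem()
  res <- run_pipeline(fx$model, fx$config, quiet = TRUE)
  orig <- names(res$phase_map$reactions$day)
  d <- data.frame(
    pair_id = orig,
    day_id = unname(res$phase_map$reactions$day),
    night_id = unname(res$phase_map$reactions$night),
    statistic = 0, p_value = 0.5, q_value = 0.5,
    significant = startsWith(orig, "T_") | orig == "R_Light",
    stringsAsFactors = FALSE)
  en <- pathway_enrichment(d, res$model)
  expect_true(all(en$K <= en$N))
  expect_true(all(en$k <= pmin(en$K, en$n)))
  expect_equal(unique(en$N), length(orig))  # every pair carries a label here
  expect_false(is.unsorted(en$p_value))
  lr <- en[en$pathway == "light reactions", ]
  expect_equal(lr$K, 3L)           # T_Photon, R_Light, R_FdOx
  expect_equal(lr$k, 2L)           # T_Photon and R_Light flagged
  expect_equal(lr$p_value,
               hyper_tail_oracle(lr$N, lr$K, lr$n, lr$k), tolerance = 1e-12)
  # degenerate corners
  k0 <- en[en$k == 0, ]
  if (nrow(k0)) expect_true(all(k0$p_value == 1))

  unl <- res$model
  for (rid in names(unl$reactions)) unl$reactions[[rid]]$pathway <- NULL
  expect_error(pathway_enrichment(d, unl), "pathway label")
})

test_that("a pathway covering the whole universe is never enriched", {
  m <- tiny_chain_model()
  for (rid in names(m$reactions)) m$reactions[[rid]]$pathway <- "everything"
  cfg <- pipeline_config(photon_reaction_ids = "EX_A")
  dup <- duplicate_phases(m, cfg)
  d <- data.frame(pair_id = names(dup$phase_map$reactions$day),
                  day_id = unname(dup$phase_map$reactions$day),
                  night_id = unname(dup$phase_map$reactions$night),
                  statistic = 0, p_value = 0.01, q_value = 0.01,
                  significant = c(TRUE, TRUE, FALSE),
                  stringsAsFactors = FALSE)
  en <- pathway_enrichment(d, dup$model)
  expect_equal(nrow(en), 1L)
  expect_equal(en$k, en$n)
  expect_equal(en$p_value, 1)
})

test_that("PCA overlap agrees with a direct eigendecomposition oracle", {
  set.seed(31)
  n_pairs <- 3; n_samp <- 10
  day <- matrix(rnorm(n_pairs * n_samp, mean = 5), n_pairs)
  night <- matrix(rnorm(n_pairs * n_samp), n_pairs)
  M <- rbind(day, night)
  rownames(M) <- c(paste0("r", 1:3, "_Day"), paste0("r", 1:3, "_Night"))
  sm <- structure(list(reaction_ids = rownames(M), samples = M, seed = 0),
                  class = "sample_matrix")
  d <- data.frame(pair_id = paste0("r", 1:3),
                  day_id = paste0("r", 1:3, "_Day"),
                  night_id = paste0("r", 1:3, "_Night"),
                  statistic = 0, p_value = 0.001, q_value = 0.001,
                  significant = TRUE, stringsAsFactors = FALSE)
  got <- pca_overlap(sm, d, distance_threshold = 1)

  Xc <- M - rowMeans(M)
  eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
  expect_equal(got$explained_variance,
               eg$values[1:2] / sum(eg$values), tolerance = 1e-9)
  scores <- Xc %*% svd(Xc)$v[, 1:2]   # equivalent row coordinates
  dist_oracle <- unname(sqrt(rowSums((scores[1:3, ] - scores[4:6, ])^2)))
  expect_equal(got$pairs$distance, dist_oracle, tolerance = 1e-9)
  expect_identical(got$pairs$overlapping, dist_oracle <= 1)
  expect_equal(got$overlap_fraction, mean(dist_oracle <= 1))
})

test_that("identical day/night rows overlap at distance zero", {
  x <- matrix(rnorm(30), 3)
  M <- rbind(x, x)
  rownames(M) <- c(paste0("r", 1:3, "_Day"), paste0("r", 1:3, "_Night"))
  sm <- structure(list(reaction_ids = rownames(M), samples = M, seed = 0),
                  class = "sample_matrix")
  d <- data.frame(pair_id = paste0("r", 1:3),
                  day_id = paste0("r", 1:3, "_Day"),
                  night_id = paste0("r", 1:3, "_Night"),
                  statistic = 0, p_value = 0, q_value = 0,
                  significant = TRUE, stringsAsFactors = FALSE)
  got <- pca_overlap(sm, d)
  expect_equal(got$pairs$distance, rep(0, 3), tolerance = 1e-9)
  expect_true(all(got$pairs$overlapping))
  expect_equal(got$overlap_fraction, 1)
})

test_that("duplicating every row leaves components and distances unchanged", {
  set.seed(41)
  M <- matrix(rnorm(60, sd = 3), 6, 10)
  rownames(M) <- c(paste0("r", 1:3, "_Day"), paste0("r", 1:3, "_Night"))
  sm1 <- structure(list(reaction_ids = rownames(M), samples = M, seed = 0),
                   class = "sample_matrix")
  d1 <- data.frame(pair_id = paste0("r", 1:3),
                   day_id = paste0("r", 1:3, "_Day"),
                   night_id = paste0("r", 1:3, "_Night"),
                   statistic = 0, p_value = 0, q_value = 0,
                   significant = TRUE, stringsAsFactors = FALSE)
  M2 <- rbind(M, M)
  rownames(M2) <- c(paste0("s", 1:3, "_Day"), paste0("s", 1:3, "_Night"),
                    paste0("t", 1:3, "_Day"), paste0("t", 1:3, "_Night"))
  sm2 <- structure(list(reaction_ids = rownames(M2), samples = M2, seed = 0),
                   class = "sample_matrix")
  d2 <- data.frame(pair_id = c(paste0("s", 1:3), paste0("t", 1:3)),
                   day_id = rownames(M2)[c(1:3, 7:9)],
                   night_id = rownames(M2)[c(4:6, 10:12)],
                   statistic = 0, p_value = 0, q_value = 0,
                   significant = TRUE, stringsAsFactors = FALSE)
  g1 <- pca_overlap(sm1, d1)
  g2 <- pca_overlap(sm2, d2)
  expect_equal(g1$explained_variance, g2$explained_variance, tolerance = 1e-9)
  expect_equal(rep(g1$pairs$distance, 2), g2$pairs$distance, tolerance = 1e-9)
})

test_that("fewer than three significant pairs is an error", {
  np <- make_null_sample_pairs(5, 10, seed = 1)
  d <- differential_reactions(np$samples, np$phase_map)
  d$significant <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_error(pca_overlap(np$samples, d), "at least 3")
})

test_that("the DFA chain is bit-reproducible given its parameters", {
  np1 <- make_null_sample_pairs(20, 30, seed = 77, effect_size = 2)
  np2 <- make_null_sample_pairs(20, 30, seed = 77, effect_size = 2)
  expect_identical(np1$samples$samples, np2$samples$samples)
  d1 <- differential_reactions(np1$samples, np1$phase_map)
  d2 <- differential_reactions(np2$samples, np2$phase_map)
  expect_identical(d1, d2)
  p1 <- pca_overlap(np1$samples, d1)
  p2 <- pca_overlap(np2$samples, d2)
  expect_identical(p1, p2)
})
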