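#' Test day/night reaction pairs for differential flux
#'
#' For every original reaction with day and night copies in the phase map,
#' compares the day copy's sampled flux row against the night copy's with a
#' two-sample rank test (two-sided Mann-Whitney / Wilcoxon by default,
#' Kolmogorov-Smirnov behind `method = "ks"`), then corrects the p-values
#' across all pairs with Benjamini-Hochberg. A pair is significant when its
#' adjusted p-value (q-value) is below `alpha`.
#'
#' @param samples A `sample_matrix` from [sample_fluxes()] (or a compatible
#'   object) containing both phase copies of every paired reaction.
#' @param phase_map The phase map from [duplicate_phases()] /
#'   [run_pipeline()].
#' @param alpha Significance level on the BH-adjusted p-values (default 0.05).
#' @param method Rank test to use: `"wilcoxon"` (default) or `"ks"`.
#' @return A data.frame with one row per pair: `pair_id` (original reaction
#'   id), `day_id`, `night_id`, `statistic`, `p_value`, `q_value`,
#'   `significant`.
#' @export
differential_reactions <- function(samples, phase_map, alpha = 0.05,
                                   method = c("wilcoxon", "ks")) {
  method <- match.arg(method)
  orig <- names(phase_map$reactions$day)
  day_ids <- unname(phase_map$reactions$day)
  night_ids <- unname(phase_map$reactions$night)
  have <- rownames(samples$samples)
  missing <- c(setdiff(day_ids, have), setdiff(night_ids, have))
  if (length(missing))
    stop("sample matrix lacks phase copies: ",
         paste(missing, collapse = ", "), call. = FALSE)

  res <- lapply(seq_along(orig), function(i) {
    x <- samples$samples[day_ids[[i]], ]
    y <- samples$samples[night_ids[[i]], ]
    if (max(abs(c(x, y) - x[[1]])) == 0) {
      # both rows one identical constant: no evidence of any difference
      stat <- length(x) * length(y) / 2
      p <- 1
    } else if (method == "wilcoxon") {
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    c(stat = stat, p = min(max(p, 0), 1))
  })
  stat <- vapply(res, `[[`, 0, "stat")
  p <- vapply(res, `[[`, 0, "p")
  q <- stats::p.adjust(p, method = "BH")
  data.frame(pair_id = orig, day_id = day_ids, night_id = night_ids,
             statistic = stat, p_value = p, q_value = q,
             significant = q < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hypergeometric pathway enrichment of differential reactions
#'
#' The universe is the set of reaction pairs carrying a pathway label (pairs
#' without a label are excluded). For each pathway with `K` labelled pairs,
#' of which `k` are significant out of `n` significant pairs in a universe of
#' `N`, the enrichment p-value is the upper-tail hypergeometric probability
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Results are sorted by
#' p-value.
#'
#' @param diff Result of [differential_reactions()].
#' @param model The diel model the pairs come from (source of the pathway
#'   labels; phase copies inherit their original reaction's label).
#' @return A data.frame with columns `pathway`, `k`, `K`, `n`, `N`,
#'   `p_value`, sorted by `p_value`.
#' @export
pathway_enrichment <- function(diff, model) {
  pw <- vapply(diff$day_id, function(rid) {
    r <- model$reactions[[rid]]
    if (is.null(r) || is.null(r$pathway)) NA_character_ else r$pathway
  }, "")
  keep <- !is.na(pw)
  if (!any(keep))
    stop("no reaction has a pathway label; enrichment is undefined",
         call. = FALSE)
  pw <- pw[keep]
  sig <- diff$significant[keep]
  N <- length(pw)
  n <- sum(sig)
  paths <- sort(unique(pw))
  K <- vapply(paths, function(p) sum(pw == p), 0L)
  k <- vapply(paths, function(p) sum(sig & pw == p), 0L)
  p_val <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(pathway = paths, k = k, K = K, n = n, N = N,
                    p_value = p_val, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$pathway), , drop = FALSE]
}

#' PCA overlap of significant day/night reaction pairs
#'
#' Builds a matrix whose rows are the day and night copies of every
#' significant pair and whose columns are their sampled fluxes, mean-centers
#' each row across samples (no unit-variance scaling, so flux magnitude
#' separation is preserved), and computes the principal components of the
#' row points by singular value decomposition. A pair overlaps when the
#' Euclidean distance between its day point and its night point in the
#' (PC1, PC2) plane is at most `distance_threshold` (default 1).
#'
#' @param samples A `sample_matrix` covering all significant pair copies.
#' @param diff Result of [differential_reactions()]; at least 3 pairs must be
#'   significant.
#' @param distance_threshold Maximum (PC1, PC2) Euclidean distance for a
#'   day/night point pair to be considered overlapping.
#' @return A list with `explained_variance` (ratios for PC1 and PC2),
#'   `pairs` (data.frame: `pair_id`, `distance`, `overlapping`), and
#'   `overlap_fraction`.
#' @export
pca_overlap <- function(samples, diff, distance_threshold = 1) {
  sig <- diff[diff$significant, , drop = FALSE]
  ns <- nrow(sig)
  if (ns < 3L)
    stop("PCA overlap needs at least 3 significant pairs (got ", ns, ")",
         call. = FALSE)
  ids <- c(sig$day_id, sig$night_id)
  missing <- setdiff(ids, rownames(samples$samples))
  if (length(missing))
    stop("sample matrix lacks rows: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- samples$samples[ids, , drop = FALSE]
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  if (tot <= .Machine$double.eps) {
    scores <- matrix(0, nrow(Xc), 2)
    explained <- c(0, 0)
  } else {
    npc <- min(2L, length(sv$d))
    scores <- sv$u[, seq_len(npc), drop = FALSE] %*% diag(sv$d[seq_len(npc)],
                                                          npc)
    if (npc < 2L) scores <- cbind(scores, 0)
    explained <- c(sv$d^2, 0, 0)[1:2] / tot
  }
  dxy <- scores[seq_len(ns), , drop = FALSE] -
    scores[ns + seq_len(ns), , drop = FALSE]
  dist2 <- sqrt(rowSums(dxy^2))
  overlapping <- dist2 <= distance_threshold
  list(explained_variance = explained,
       pairs = data.frame(pair_id = sig$pair_id, distance = dist2,
                          overlapping = overlapping, row.names = NULL,
                          stringsAsFactors = FALSE),
       overlap_fraction = mean(overlapping))
}
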