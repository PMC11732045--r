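# Alpha-diversity statistics for OTU count tables: nonparametric richness
# (Chao1, ACE), Shannon/evenness, coverage, hypergeometric rarefaction and
# shared-OTU (Venn) counts.

.check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers", call. = FALSE)
  round(counts)
}

#' Shannon diversity index
#'
#' `H = -sum p_i log(p_i)` over OTUs with positive counts, natural
#' logarithm (required for the evenness convention `H / ln S`).
#'
#' @param counts per-OTU abundance counts (nonnegative integers)
#' @return H in nats
#' @export
shannon_diversity <- function(counts) {
  counts <- .check_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' `J = H / ln(S_obs)`, the Shannon index relative to its maximum for the
#' observed richness; 1 for a perfectly uniform community.
#'
#' @param H Shannon index in nats
#' @param S_obs observed OTU richness, >= 2
#' @return evenness in `[0, 1]` (unrounded; round to 2 decimals for table
#'   reporting)
#' @export
evenness <- function(H, S_obs) {
  if (any(S_obs < 2))
    stop("S_obs must be >= 2 (evenness undefined for a single OTU)",
         call. = FALSE)
  H / log(S_obs)
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` by default;
#' the classical form `S_obs + F1^2 / (2 F2)` is available with
#' `bias_corrected = FALSE` (it requires `F2 > 0`).
#'
#' @param S_obs observed richness
#' @param F1 number of singletons
#' @param F2 number of doubletons
#' @param bias_corrected use the bias-corrected form (default TRUE)
#' @return estimated richness (>= `S_obs`)
#' @export
chao1 <- function(S_obs, F1, F2, bias_corrected = TRUE) {
  if (any(c(S_obs, F1, F2) < 0)) stop("inputs must be >= 0", call. = FALSE)
  if (F1 + F2 > S_obs)
    stop("F1 + F2 cannot exceed S_obs", call. = FALSE)
  if (bias_corrected) {
    S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))
  } else {
    if (F2 == 0)
      stop("classical Chao1 undefined for F2 = 0; use bias_corrected = TRUE",
           call. = FALSE)
    S_obs + F1^2 / (2 * F2)
  }
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator (Chao & Lee) with the conventional
#' rare/abundant cutoff of 10 reads:
#' `S_abund + S_rare / C_ace + (F1 / C_ace) gamma^2`, where
#' `C_ace = 1 - F1 / N_rare` is the sample coverage of the rare class and
#' `gamma^2` the rare-class coefficient of variation, floored at 0.
#'
#' @param counts per-OTU abundance counts
#' @param rare_threshold abundance cutoff for the rare class (default 10)
#' @return estimated richness
#' @export
ace <- function(counts, rare_threshold = 10) {
  counts <- .check_counts(counts)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all counts are zero", call. = FALSE)
  rare <- counts[counts <= rare_threshold]
  S_abund <- as.numeric(sum(counts > rare_threshold))
  S_rare <- length(rare)
  if (S_rare == 0L) return(S_abund) # no rare class: ACE = S_obs
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  C_ace <- 1 - F1 / N_rare
  if (C_ace == 0)
    stop("every rare OTU is a singleton (rare-class coverage 0); ",
         "ACE is undefined, use chao1()", call. = FALSE)
  Fi <- tabulate(rare, nbins = rare_threshold)
  i <- seq_len(rare_threshold)
  gamma2 <- max(S_rare / C_ace * sum(i * (i - 1) * Fi) /
                  (N_rare * (N_rare - 1)) - 1, 0)
  S_abund + S_rare / C_ace + F1 / C_ace * gamma2
}

#' Sample coverage
#'
#' Two conventions: `variant = "good"` is Good's coverage
#' `100 (1 - F1/N)` (fraction of reads from already-seen OTUs);
#' `variant = "paper"` is the OTU-based ratio `100 (1 - F1/S_obs)`
#' sometimes printed under the same name in community-survey tables
#' (the convention needed to reproduce such tables cell by cell).
#'
#' @param F1 number of singletons
#' @param S_obs observed richness (needed for `"paper"`)
#' @param N total reads (needed for `"good"`)
#' @param variant `"paper"` (default) or `"good"`
#' @return coverage in percent (unrounded; report to 2 decimals)
#' @export
goods_coverage <- function(F1, S_obs = NULL, N = NULL,
                           variant = c("paper", "good")) {
  variant <- match.arg(variant)
  if (F1 < 0) stop("F1 must be >= 0", call. = FALSE)
  if (variant == "paper") {
    if (is.null(S_obs) || S_obs <= 0)
      stop("variant 'paper' needs S_obs > 0", call. = FALSE)
    if (F1 > S_obs) stop("F1 cannot exceed S_obs", call. = FALSE)
    100 * (1 - F1 / S_obs)
  } else {
    if (is.null(N) || N <= 0)
      stop("variant 'good' needs N > 0", call. = FALSE)
    if (F1 > N) stop("F1 cannot exceed N", call. = FALSE)
    100 * (1 - F1 / N)
  }
}

#' Rarefaction: expected richness in a subsample
#'
#' Expected number of OTUs observed in a random subsample of `d` reads
#' drawn without replacement. The analytic form is the hypergeometric
#' expectation `E[S_d] = sum_i (1 - choose(N - n_i, d)/choose(N, d))`
#' (computed in log space); `method = "montecarlo"` estimates the same
#' quantity by resampling and is mainly an internal cross-check.
#'
#' @param counts per-OTU abundance counts
#' @param depths subsample sizes, each between 1 and `sum(counts)`
#' @param method `"analytic"` (default) or `"montecarlo"`
#' @param n_rep Monte-Carlo replicates
#' @param seed RNG seed for the Monte-Carlo route
#' @return numeric vector of expected richness, one value per depth
#' @export
rarefy_richness <- function(counts, depths, method = c("analytic",
                                                       "montecarlo"),
                            n_rep = 1000, seed = 1) {
  method <- match.arg(method)
  counts <- .check_counts(counts)
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths < 1) || any(depths > N))
    stop("each depth must lie in [1, total reads]", call. = FALSE)
  if (any(abs(depths - round(depths)) > 1e-8))
    stop("depths must be integers", call. = FALSE)
  depths <- round(depths)
  if (method == "analytic") {
    vapply(depths, function(d) {
      # 1 - C(N - n_i, d)/C(N, d), with the ratio 0 once n_i > N - d
      lr <- ifelse(counts > N - d, -Inf,
                   lchoose(N - counts, d) - lchoose(N, d))
      sum(1 - exp(lr))
    }, numeric(1))
  } else {
    reads <- rep.int(seq_along(counts), counts)
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    vapply(depths, function(d) {
      mean(vapply(seq_len(n_rep), function(r) {
        length(unique(sample(reads, d, replace = FALSE)))
      }, numeric(1)))
    }, numeric(1))
  }
}

#' Shared-OTU (Venn) region counts for 2-3 samples
#'
#' Presence/absence overlap structure of the OTU sets of two or three
#' samples: exclusive counts, pairwise-exclusive counts and the core
#' (shared-by-all) count. Regions partition the union of observed OTUs.
#'
#' @param otu an [otu_table()] (or plain sample x OTU count matrix with
#'   sample rownames)
#' @param samples which sample ids to compare (default: all); 2 or 3
#' @return named integer vector of region counts; e.g. for samples A, B, C:
#'   `A`, `B`, `C` (exclusive), `A&B`, `A&C`, `B&C` (pairwise exclusive)
#'   and `A&B&C` (core)
#' @export
venn_counts <- function(otu, samples = rownames(otu)) {
  m <- as.matrix(otu)
  if (anyDuplicated(samples))
    stop("duplicate sample ids", call. = FALSE)
  if (!all(samples %in% rownames(m)))
    stop("unknown sample id(s): ",
         paste(setdiff(samples, rownames(m)), collapse = ", "),
         call. = FALSE)
  m <- m[samples, , drop = FALSE]
  k <- nrow(m)
  if (k < 2 || k > 3)
    stop("venn_counts supports 2 or 3 samples", call. = FALSE)
  pres <- m > 0
  pres <- pres[, colSums(pres) > 0, drop = FALSE]
  # membership pattern per OTU, e.g. "A&B"
  pat <- apply(pres, 2, function(z) paste(samples[z], collapse = "&"))
  regions <- unlist(lapply(seq_len(k), function(r) {
    utils::combn(samples, r, paste, collapse = "&")
  }))
  out <- stats::setNames(integer(length(regions)), regions)
  tab <- table(pat)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Alpha-diversity summary of one sample
#'
#' Computes the standard survey-table row block for one sample: observed
#' richness, singletons/doubletons, Chao1, ACE, Shannon, evenness and both
#' coverage conventions.
#'
#' @param counts per-OTU abundance counts for one sample
#' @return data.frame with one row and columns `n_otus`, `n_singletons`,
#'   `n_doubletons`, `chao1`, `ace`, `shannon`, `evenness`,
#'   `coverage_paper`, `coverage_good`
#' @examples
#' set.seed(1)
#' x <- table(sample(200, 500, replace = TRUE, prob = 1 / sqrt(1:200)))
#' alpha_summary(as.integer(x))
#' @export
alpha_summary <- function(counts) {
  counts <- .check_counts(counts)
  counts <- counts[counts > 0]
  S <- length(counts)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  N <- sum(counts)
  H <- shannon_diversity(counts)
  data.frame(n_otus = S, n_singletons = F1, n_doubletons = F2,
             chao1 = chao1(S, F1, F2),
             ace = ace(counts),
             shannon = H,
             evenness = if (S >= 2) evenness(H, S) else NA_real_,
             coverage_paper = goods_coverage(F1, S_obs = S),
             coverage_good = goods_coverage(F1, N = N, variant = "good"))
}
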