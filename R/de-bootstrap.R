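# Core statistics for replicate-free differential expression:
# Poisson parametric bootstrap -> per-replicate conditional binomial exact
# test -> per-gene median p -> Benjamini-Hochberg q-values -> FC/status calls.

#' Two-sided conditional binomial exact test for two sequencing libraries
#'
#' Tests equality of relative abundance of one gene between two libraries
#' without replicates. Conditional on the total \eqn{t = x_a + x_b}, under the
#' null the count in library a is Binomial(t, n_a/(n_a + n_b)), where n_a and
#' n_b are the library sizes. The two-sided p-value is computed by the method
#' of small probabilities: the sum of the probabilities of every outcome
#' \eqn{k \in [0, t]} whose point probability does not exceed that of the
#' observed count. This is the dispersion-zero limit of the negative-binomial
#' exact test used for pairwise library comparisons.
#'
#' A total of zero carries no information and returns p = 1.
#'
#' @param x_a,x_b observed counts in libraries a and b (vectors recycle).
#' @param n_a,n_b library sizes (total counts), both > 0.
#' @return vector of two-sided p-values in (0, 1].
#' @examples
#' exact_test_two_libraries(0, 10, 1e6, 1e6)  # 2/1024
#' @export
exact_test_two_libraries <- function(x_a, x_b, n_a, n_b) {
  if (any(n_a <= 0) || any(n_b <= 0)) stop("library sizes must be positive")
  if (any(x_a < 0) || any(x_b < 0)) stop("counts must be non-negative")
  if (any(x_a != floor(x_a)) || any(x_b != floor(x_b)))
    stop("counts must be integral")
  k <- max(length(x_a), length(x_b), length(n_a), length(n_b))
  x_a <- rep_len(x_a, k); x_b <- rep_len(x_b, k)
  n_a <- rep_len(n_a, k); n_b <- rep_len(n_b, k)
  binom_two_sided(x_a, x_a + x_b, n_a / (n_a + n_b))
}

# Vectorised two-sided small-probabilities p-value for x ~ Binomial(size, prob).
# The inclusion set {k : P(k) <= P(x)*(1+eps)} is a union of two tails because
# the binomial pmf is unimodal; the far-tail cutoff is located by binary
# search, so the cost is O(log size) density evaluations per element.
binom_two_sided <- function(x, size, prob, eps = 1e-10) {
  k <- max(length(x), length(size), length(prob))
  x <- rep_len(x, k); size <- rep_len(size, k); prob <- rep_len(prob, k)
  p <- rep(1, k)
  act <- which(size > 0)
  if (!length(act)) return(p)

  x <- x[act]; size <- size[act]; prob <- prob[act]
  d_obs <- stats::dbinom(x, size, prob)
  thresh <- d_obs * (1 + eps)
  m <- pmin(pmax(floor((size + 1) * prob), 0), size)  # a mode of the pmf
  d_mode <- stats::dbinom(m, size, prob)

  res <- rep(1, length(act))
  nontriv <- which(d_mode > thresh)  # otherwise every outcome is included

  if (length(nontriv)) {
    xi <- x[nontriv]; si <- size[nontriv]; pi <- prob[nontriv]
    mi <- m[nontriv]; th <- thresh[nontriv]
    left <- xi <= mi  # observed on the left flank: search the right tail
    out <- numeric(length(nontriv))

    if (any(left)) {
      xl <- xi[left]; sl <- si[left]; pl <- pi[left]
      ml <- mi[left]; tl <- th[left]
      # smallest k in (m, size] with P(k) <= thresh; dbinom decreasing there
      lo <- ml; hi <- sl + 1
      while (any(hi - lo > 1L)) {
        mid <- (lo + hi) %/% 2
        take <- stats::dbinom(pmin(mid, sl), sl, pl) > tl & mid <= sl
        lo <- ifelse(take, mid, lo)
        hi <- ifelse(take, hi, mid)
      }
      out[left] <- stats::pbinom(xl, sl, pl) +
        stats::pbinom(hi - 1, sl, pl, lower.tail = FALSE)
    }
    if (any(!left)) {
      xr <- xi[!left]; sr <- si[!left]; pr <- pi[!left]
      mr <- mi[!left]; tr <- th[!left]
      # largest k in [0, m) with P(k) <= thresh; dbinom increasing there
      lo <- rep(-1, length(xr)); hi <- mr
      while (any(hi - lo > 1L)) {
        mid <- (lo + hi) %/% 2
        take <- stats::dbinom(pmax(mid, 0), sr, pr) <= tr & mid >= 0
        lo <- ifelse(take, mid, lo)
        hi <- ifelse(take, hi, mid)
      }
      out[!left] <- stats::pbinom(xr - 1, sr, pr, lower.tail = FALSE) +
        ifelse(lo >= 0, stats::pbinom(lo, sr, pr), 0)
    }
    res[nontriv] <- pmin(out, 1)
  }
  p[act] <- res
  p
}

#' Negative-binomial exact test at fixed dispersion
#'
#' Sensitivity-analysis companion to \code{\link{exact_test_two_libraries}}:
#' conditions on the total \eqn{t = x_a + x_b} under a negative-binomial
#' model with user-fixed dispersion (no dispersion is estimable from two
#' unreplicated libraries). Under H0 the fitted means split the total by
#' library size, the joint probability of every split \eqn{(k, t-k)} is
#' normalised over \eqn{k \in [0, t]}, and the two-sided p-value sums the
#' splits no more probable than the observed one. As dispersion approaches 0
#' this converges to the conditional binomial test.
#'
#' @param x_a,x_b observed counts (vectors recycle).
#' @param n_a,n_b library sizes, both > 0.
#' @param dispersion negative-binomial dispersion phi > 0 (variance
#'   mu + phi mu^2).
#' @return vector of two-sided p-values in (0, 1].
#' @export
nb_exact_test <- function(x_a, x_b, n_a, n_b, dispersion) {
  if (any(n_a <= 0) || any(n_b <= 0)) stop("library sizes must be positive")
  if (any(x_a < 0) || any(x_b < 0)) stop("counts must be non-negative")
  if (dispersion <= 0)
    stop("dispersion must be > 0; use exact_test_two_libraries for Poisson")
  k <- max(length(x_a), length(x_b), length(n_a), length(n_b))
  x_a <- rep_len(x_a, k); x_b <- rep_len(x_b, k)
  n_a <- rep_len(n_a, k); n_b <- rep_len(n_b, k)
  size <- 1 / dispersion
  vapply(seq_len(k), function(i) {
    t <- x_a[i] + x_b[i]
    if (t == 0) return(1)
    pr <- n_a[i] / (n_a[i] + n_b[i])
    ks <- 0:t
    logw <- stats::dnbinom(ks, size = size, mu = t * pr, log = TRUE) +
      stats::dnbinom(t - ks, size = size, mu = t * (1 - pr), log = TRUE)
    w <- exp(logw - max(logw))
    w <- w / sum(w)
    min(1, sum(w[w <= w[x_a[i] + 1] * (1 + 1e-10)]))
  }, numeric(1))
}

#' Poisson resampling of a count matrix (parametric bootstrap draw)
#'
#' Draws one pseudo-replicate of an unreplicated experiment: every entry is
#' replaced by an independent Poisson variate whose mean is the observed count
#' itself (the observed raw expression is taken as the Poisson parameter
#' lambda, per gene and per library). Observed zeros therefore stay zero.
#'
#' @param counts validated count matrix.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return matrix of the same shape and dimnames.
#' @export
poisson_resample <- function(counts, seed) {
  counts <- validate_count_matrix(counts)
  set.seed(as.integer(seed))
  sim <- matrix(stats::rpois(length(counts), lambda = counts),
                nrow = nrow(counts), dimnames = dimnames(counts))
  storage.mode(sim) <- "double"
  sim
}

# Prefix-stable per-replicate seed stream: growing B extends the stream
# without changing the seeds of earlier replicates.
replicate_seeds <- function(master_seed, B) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, B)
}

#' Bootstrap median p-values for one contrast
#'
#' Runs the full pseudo-replication procedure for one pair of libraries: for
#' each of B replicates the whole matrix is Poisson-resampled, library sizes
#' are recomputed from the pseudo-matrix, and the conditional binomial exact
#' test is applied gene by gene. The per-gene median of the B p-values is
#' returned (for even B, the mean of the two central order statistics).
#'
#' @param counts validated count matrix.
#' @param contrast character vector \code{c(a, b)} of two library ids; the
#'   contrast is read as b vs a.
#' @param B number of bootstrap replicates (default 100).
#' @param seed master seed; replicate r uses an independently derived seed so
#'   that increasing B leaves earlier replicates unchanged.
#' @param test per-replicate test: \code{"binomial"} (conditional binomial,
#'   default) or \code{"nb"} (negative-binomial at fixed \code{dispersion},
#'   for sensitivity analysis).
#' @param dispersion fixed dispersion for \code{test = "nb"}.
#' @return named vector of median p-values, one per gene.
#' @export
bootstrap_pvalues <- function(counts, contrast, B = 100L, seed = 1L,
                              test = c("binomial", "nb"), dispersion = 0) {
  counts <- validate_count_matrix(counts)
  test <- match.arg(test)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer")
  if (length(contrast) != 2L || !all(contrast %in% colnames(counts)))
    stop("contrast must name two libraries present in the matrix")
  seeds <- replicate_seeds(seed, B)
  pm <- matrix(NA_real_, nrow(counts), B)
  for (r in seq_len(B)) {
    pseudo <- poisson_resample(counts, seeds[r])
    xa <- pseudo[, contrast[1]]
    xb <- pseudo[, contrast[2]]
    na <- sum(xa); nb <- sum(xb)
    pm[, r] <- if (na > 0 && nb > 0) {
      if (test == "binomial")
        binom_two_sided(xa, xa + xb, na / (na + nb))
      else
        nb_exact_test(xa, xb, na, nb, dispersion)
    } else rep(1, nrow(counts))
  }
  p_med <- apply(pm, 1L, stats::median)
  names(p_med) <- rownames(counts)
  p_med
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j} capped at 1, mapped back to
#' input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values, same order and names.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold change between two libraries on the counts-per-million scale
#'
#' FC = CPM_b / CPM_a with CPM = 1e6 * count / library size; the contrast is
#' read as b vs a (e.g. fold change of TD vs TW uses a = TW, b = TD). A zero
#' numerator with a positive denominator yields FC = 0; a zero denominator
#' with a positive numerator yields Inf; both zero yields NA (undefined,
#' flagged downstream as undetermined).
#'
#' @param x_a,x_b counts in libraries a and b.
#' @param n_a,n_b library sizes, both > 0.
#' @return vector of fold changes.
#' @export
fold_change <- function(x_a, x_b, n_a, n_b) {
  if (any(n_a <= 0) || any(n_b <= 0)) stop("library sizes must be positive")
  cpm_a <- 1e6 * x_a / n_a
  cpm_b <- 1e6 * x_b / n_b
  fc <- ifelse(cpm_a == 0 & cpm_b == 0, NA_real_,
        ifelse(cpm_a == 0, Inf, cpm_b / cpm_a))
  fc
}

#' Classify regulation status from fold change and q-value
#'
#' A gene is called up-regulated when FC > 1.5 and q below the FDR threshold,
#' down-regulated when FC <= 0.5 (inclusive) and q below the threshold;
#' an undefined fold change (zero expression in both libraries) is
#' undetermined; anything else is not significant.
#'
#' @param fc fold change (b vs a), possibly NA or Inf.
#' @param q q-value in [0, 1].
#' @param fdr_threshold FDR cut-off (default 0.001).
#' @param fc_up,fc_down fold-change cut-offs (defaults 1.5 strict, 0.5
#'   inclusive).
#' @return character vector with levels up / down / not_significant /
#'   undetermined.
#' @export
classify_deg <- function(fc, q, fdr_threshold = 0.001,
                         fc_up = 1.5, fc_down = 0.5) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q must lie in [0, 1]")
  status <- rep("not_significant", length(fc))
  status[is.na(fc)] <- "undetermined"
  sig <- !is.na(fc) & !is.na(q) & q < fdr_threshold
  status[sig & fc > fc_up] <- "up"
  status[sig & fc <= fc_down] <- "down"
  status
}

#' Transcripts per million
#'
#' Length-normalised abundance: \eqn{TPM_g = 10^6 r_g / \sum_h r_h} with
#' \eqn{r_g = count_g / length_g}. An all-zero count vector maps to all-zero
#' TPM. The companion log transform used for cross-platform comparison is
#' \code{log2(tpm + 1)}.
#'
#' @param counts per-gene counts.
#' @param lengths per-gene transcript lengths in nt, all > 0.
#' @return vector of TPM values summing to 1e6 when any count is positive.
#' @export
tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) stop("counts/lengths length mismatch")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) return(rep(0, length(counts)))
  1e6 * rate / tot
}

#' Full differential-expression call for one contrast
#'
#' Combines the bootstrap median p-values, BH q-values, fold change and
#' regulation status into one per-gene table.
#'
#' @param counts validated count matrix.
#' @param contrast character vector \code{c(a, b)}; read as b vs a.
#' @param B bootstrap replicates (default 100).
#' @param seed master seed.
#' @param fdr_threshold FDR cut-off for status calls (default 0.001).
#' @param fc_up,fc_down fold-change cut-offs.
#' @param test,dispersion per-replicate test strategy, see
#'   \code{\link{bootstrap_pvalues}}.
#' @return data.frame with columns gene_id, contrast, fc, p_median, q, status.
#' @export
run_de <- function(counts, contrast, B = 100L, seed = 1L,
                   fdr_threshold = 0.001, fc_up = 1.5, fc_down = 0.5,
                   test = c("binomial", "nb"), dispersion = 0) {
  counts <- validate_count_matrix(counts)
  p_med <- bootstrap_pvalues(counts, contrast, B = B, seed = seed,
                             test = test, dispersion = dispersion)
  q <- bh_fdr(p_med)
  xa <- counts[, contrast[1]]
  xb <- counts[, contrast[2]]
  fc <- fold_change(xa, xb, sum(xa), sum(xb))
  data.frame(
    gene_id = rownames(counts),
    contrast = paste(contrast[2], "vs", contrast[1]),
    fc = fc,
    p_median = unname(p_med),
    q = unname(q),
    status = classify_deg(fc, q, fdr_threshold, fc_up, fc_down),
    stringsAsFactors = FALSE
  )
}
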