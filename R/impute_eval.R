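#' Li-Stephens evaluator parameters
#'
#' The leave-one-out evaluator uses a haploid hidden Markov model over
#' reference haplotypes: the hidden state is the reference haplotype
#' being copied; between adjacent scaffold sites the copied haplotype
#' switches with probability \code{1 - exp(-rho * d)} (distance \code{d}
#' in bp), landing uniformly on any reference haplotype; the emitted
#' allele matches the copied haplotype with probability
#' \code{1 - emission_error}.
#'
#' @param emission_error allele miscopy probability (0 < eps < 0.5).
#' @param switch_rate switch intensity rho per bp (>= 0).
#' @param ref_cap cap on the number of reference haplotypes used
#'   (default \code{Inf}: all); when capped, the first \code{ref_cap}
#'   haplotypes in panel order are used, deterministically.
#' @return list of class \code{ls_params}.
#' @export
ls_params <- function(emission_error = 0.01, switch_rate = 1e-6,
                      ref_cap = Inf) {
  stopifnot(emission_error > 0, emission_error < 0.5, switch_rate >= 0,
            ref_cap >= 1)
  structure(list(emission_error = emission_error,
                 switch_rate = switch_rate, ref_cap = ref_cap),
            class = "ls_params")
}

# Forward-backward posterior state probabilities for one observed
# haplotype.  ref: H x S binary matrix of reference haplotypes at
# scaffold sites; obs: length-S observed alleles; pos: scaffold
# positions.  Returns H x S posterior matrix (columns sum to 1).
.ls_posterior <- function(ref, obs, pos, ls) {
  H <- nrow(ref); S <- ncol(ref)
  eps <- ls$emission_error
  q <- if (S > 1) 1 - exp(-ls$switch_rate * diff(pos)) else numeric(0)
  emit <- ifelse(ref == matrix(obs, H, S, byrow = TRUE), 1 - eps, eps)
  alpha <- matrix(0, H, S)
  a <- emit[, 1] / H
  alpha[, 1] <- a / sum(a)
  if (S > 1) for (s in 1:(S - 1)) {
    a <- ((1 - q[s]) * alpha[, s] + q[s] / H) * emit[, s + 1]
    alpha[, s + 1] <- a / sum(a)
  }
  beta <- matrix(1 / H, H, S)
  b <- rep(1, H)
  if (S > 1) for (s in (S - 1):1) {
    v <- b * emit[, s + 1]
    b <- (1 - q[s]) * v + q[s] * mean(v)
    b <- b / sum(b)
    beta[, s] <- b
  }
  post <- alpha * beta
  sweep(post, 2, colSums(post), "/")
}

# linear interpolation weights of eval positions between scaffold
# positions: returns left/right scaffold indices and left weight
.interp_weights <- function(scaffold_pos, eval_pos) {
  S <- length(scaffold_pos)
  left <- findInterval(eval_pos, scaffold_pos)
  right <- pmin(left + 1L, S)
  left <- pmax(left, 1L)
  w <- rep(1, length(eval_pos))
  inside <- right > left
  w[inside] <- (scaffold_pos[right[inside]] - eval_pos[inside]) /
    (scaffold_pos[right[inside]] - scaffold_pos[left[inside]])
  list(left = left, right = right, w = w)
}

#' Impute dosages for one sample by leave-one-out Li-Stephens
#'
#' Removes the focal sample's two haplotypes from the panel, runs the
#' haploid forward-backward over the remaining reference haplotypes at
#' the scaffold sites, interpolates posterior state probabilities
#' linearly in physical distance at each evaluation site, and returns
#' the diploid dosage (sum over the two focal haplotypes of the
#' posterior-weighted reference alleles), bounded in \code{[0, 2]}.
#' Evaluation sites that are themselves on the scaffold are returned as
#' the true genotype and flagged in the \code{observed} attribute.
#'
#' @param panel a \code{hap_panel} (biallelic scaffold and eval sites).
#' @param sample_id focal sample.
#' @param scaffold character vector of scaffold (typed) vids.
#' @param eval_sites character vector of vids to impute.
#' @param ls a \code{\link{ls_params}}.
#' @return named numeric dosage vector over \code{eval_sites}, with a
#'   logical attribute \code{observed}.
#' @export
impute_dosage <- function(panel, sample_id, scaffold, eval_sites,
                          ls = ls_params()) {
  js <- match(scaffold, panel$sites$vid)
  je <- match(eval_sites, panel$sites$vid)
  if (anyNA(js)) stop("scaffold vid not in panel")
  if (anyNA(je)) stop("eval vid not in panel")
  if (length(js) == 0) stop("zero scaffold sites")
  if (any(n_alt_alleles(panel)[c(js, je)] > 1L))
    stop("imputation evaluator accepts only biallelic sites")
  si <- match(sample_id, panel$samples$sample_id)
  if (is.na(si)) stop("unknown sample: ", sample_id)
  focal_rows <- c(2L * si - 1L, 2L * si)
  ref_rows <- setdiff(seq_len(nrow(panel$alleles)), focal_rows)
  if (length(ref_rows) == 0) stop("no reference haplotypes left")
  if (is.finite(ls$ref_cap) && length(ref_rows) > ls$ref_cap)
    ref_rows <- ref_rows[seq_len(ls$ref_cap)]

  ord <- order(panel$sites$pos[js])
  js <- js[ord]
  spos <- panel$sites$pos[js]
  ref <- panel$alleles[ref_rows, js, drop = FALSE]
  refE <- panel$alleles[ref_rows, je, drop = FALSE]
  iw <- .interp_weights(spos, panel$sites$pos[je])

  dose <- numeric(length(je))
  for (h in focal_rows) {
    obs <- panel$alleles[h, js]
    post <- .ls_posterior(ref, obs, spos, ls)
    # M[s, e] = sum_k post[k, s] * refE[k, e]; dosage interpolates rows
    M <- crossprod(post, refE)
    dose <- dose + iw$w * M[cbind(iw$left, seq_along(je))] +
      (1 - iw$w) * M[cbind(iw$right, seq_along(je))]
  }
  dose <- pmin(pmax(dose, 0), 2)
  observed <- eval_sites %in% scaffold
  if (any(observed)) {
    truth <- panel$alleles[focal_rows[1], je] + panel$alleles[focal_rows[2], je]
    dose[observed] <- truth[observed]
  }
  structure(setNames(dose, eval_sites), observed = observed)
}

# assign per-population MAF values to bins defined by increasing edges;
# returns integer bin (1 = lowest) or NA below the first edge
.maf_bin <- function(m, edges) {
  b <- findInterval(m, edges, left.open = TRUE)   # bins (e1,e2], ... (ek, ..]
  ifelse(m <= edges[1], NA_integer_, b)
}

.bin_labels <- function(edges) {
  k <- length(edges)
  c(sprintf("(%g-%g]", edges[-k] * 100, edges[-1] * 100),
    sprintf(">%g", edges[k] * 100))
}

#' Leave-one-out imputation accuracy, stratified by population and MAF
#'
#' For each sample in turn, its haplotypes are dropped from the
#' reference and its genotypes at the evaluation sites are imputed from
#' the scaffold.  Accuracy per evaluation site and population is the
#' squared Pearson correlation (times 100) between imputed dosage and
#' the true genotype across the population's samples, averaged within
#' population-specific MAF bins.  Sites monomorphic in a population,
#' below the lowest bin edge, or with zero dosage variance are excluded
#' from that population's cells and counted.
#'
#' @param panel a \code{hap_panel}.
#' @param scaffold character vector of typed vids.
#' @param eval_sites vids to impute and score.
#' @param ls a \code{\link{ls_params}}.
#' @param bins increasing MAF bin edges (default 0.005, 0.01, 0.05,
#'   giving bins 0.5-1\%, 1-5\%, >5\%).
#' @param accuracy "r2" (default, squared Pearson x100) or "r"
#'   (plain correlation x100).
#' @return object of class \code{imputation_report}: \code{accuracy}
#'   and \code{n_sites} matrices (population x bin), \code{per_site}
#'   data.frame, \code{n_excluded} per population.  Populations with
#'   fewer than 3 samples are reported as \code{NA}.
#' @export
loo_accuracy <- function(panel, scaffold, eval_sites, ls = ls_params(),
                         bins = c(0.005, 0.01, 0.05),
                         accuracy = c("r2", "r")) {
  accuracy <- match.arg(accuracy)
  stopifnot(all(diff(bins) > 0))
  je <- match(eval_sites, panel$sites$vid)
  if (anyNA(je)) stop("eval vid not in panel")
  n_samp <- nrow(panel$samples)
  dosages <- matrix(NA_real_, n_samp, length(eval_sites),
                    dimnames = list(panel$samples$sample_id, eval_sites))
  for (i in seq_len(n_samp)) {
    dosages[i, ] <- impute_dosage(panel, panel$samples$sample_id[i],
                                  scaffold, eval_sites, ls)
  }
  truth <- panel$alleles[seq(1, 2 * n_samp, 2), je, drop = FALSE] +
    panel$alleles[seq(2, 2 * n_samp, 2), je, drop = FALSE]
  dimnames(truth) <- dimnames(dosages)
  .score_report(panel, dosages, truth, eval_sites, bins, accuracy)
}

# shared scoring: per-site per-population correlation, binned means
.score_report <- function(panel, dosages, truth, eval_sites, bins,
                          accuracy) {
  pops <- sort(unique(panel$samples$population))
  labels <- .bin_labels(bins)
  acc <- matrix(NA_real_, length(pops), length(labels),
                dimnames = list(pops, labels))
  nmat <- matrix(0L, length(pops), length(labels),
                 dimnames = list(pops, labels))
  excl <- setNames(integer(length(pops)), pops)
  per_site <- list()
  for (p in pops) {
    rows <- which(panel$samples$population == p)
    if (length(rows) < 3) { excl[p] <- length(eval_sites); next }
    mafs <- .maf_vector(panel, p)[eval_sites]
    bin <- .maf_bin(mafs, bins)
    r2s <- rep(NA_real_, length(eval_sites))
    for (k in seq_along(eval_sites)) {
      if (is.na(bin[k])) next
      d <- dosages[rows, k]; g <- truth[rows, k]
      if (sd(d) == 0 || sd(g) == 0) { bin[k] <- NA; next }
      r <- cor(d, g)
      r2s[k] <- if (accuracy == "r2") 100 * r^2 else 100 * r
    }
    excl[p] <- sum(is.na(bin))
    per_site[[p]] <- data.frame(population = p, vid = eval_sites,
                                maf = unname(mafs), bin = bin,
                                accuracy = r2s, stringsAsFactors = FALSE)
    for (b in seq_along(labels)) {
      sel <- which(bin == b)
      nmat[p, b] <- length(sel)
      if (length(sel)) acc[p, b] <- mean(r2s[sel])
    }
  }
  structure(list(accuracy = acc, n_sites = nmat,
                 n_excluded = excl,
                 per_site = do.call(rbind, per_site),
                 bins = bins),
            class = "imputation_report")
}

#' @export
print.imputation_report <- function(x, digits = 2, ...) {
  cat("imputation_report (accuracy = 100 x r^2):\n")
  print(round(x$accuracy, digits))
  if (!is.null(x$delta)) {
    cat("delta (with - without custom content), percentage points:\n")
    print(round(x$delta, digits))
  }
  invisible(x)
}

#' Compare imputation accuracy between two scaffolds
#'
#' Runs \code{\link{loo_accuracy}} under a scaffold with custom content
#' and one without, on identical evaluation sites and samples, and
#' reports the per-cell accuracy difference in percentage points.
#'
#' @param panel a \code{hap_panel}.
#' @param with_custom,without_custom character vectors of scaffold vids;
#'   \code{without_custom} must be a subset of \code{with_custom}.
#' @param eval_sites vids to impute (must be disjoint from
#'   \code{with_custom}).
#' @param ls a \code{\link{ls_params}}.
#' @param bins MAF bin edges.
#' @param accuracy "r2" or "r".
#' @return an \code{imputation_report} for the with-custom scaffold,
#'   with extra fields \code{without} (the other report) and
#'   \code{delta} (accuracy(with) - accuracy(without), percentage
#'   points, population x bin).
#' @export
compare_scaffolds <- function(panel, with_custom, without_custom,
                              eval_sites, ls = ls_params(),
                              bins = c(0.005, 0.01, 0.05),
                              accuracy = c("r2", "r")) {
  accuracy <- match.arg(accuracy)
  if (!all(without_custom %in% with_custom))
    stop("without_custom must be a subset of with_custom")
  if (any(eval_sites %in% with_custom))
    stop("eval_sites must be disjoint from the with-custom scaffold")
  rep_with <- loo_accuracy(panel, with_custom, eval_sites, ls, bins,
                           accuracy)
  rep_without <- loo_accuracy(panel, without_custom, eval_sites, ls, bins,
                              accuracy)
  rep_with$without <- rep_without
  rep_with$delta <- rep_with$accuracy - rep_without$accuracy
  rep_with
}
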