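## p-distances with pairwise deletion, distance matrices, group means,
## fold differences and calibration-ratio divergence dating.

#' p-distance of an aligned pair
#'
#' Pairwise deletion: comparable sites are the columns with both bases in
#' `{A,C,G,T}` (gap and N columns excluded); the p-distance is the fraction
#' of comparable sites that differ.
#'
#' @param aln an `AlignedPair`, or a list with `gappedA`/`gappedB`.
#' @return list with `ndiff`, `comparable_sites`, `p`.
#' @export
p_distance <- function(aln) {
  ca <- str2chars(aln$gappedA); cb <- str2chars(aln$gappedB)
  acgt <- c("A", "C", "G", "T")
  ok <- ca %in% acgt & cb %in% acgt
  n <- sum(ok)
  if (n == 0L) stop("zero comparable sites")
  nd <- sum(ok & ca != cb)
  list(ndiff = nd, comparable_sites = n, p = nd / n)
}

#' Pairwise p-distance matrix over a set of sequences
#'
#' Each pair is aligned independently ([align_auto()]) and its
#' pairwise-deletion p-distance computed; no joint multiple alignment is
#' built.
#'
#' @param seqs named character vector (or named list) of DNA sequences.
#' @param ... passed to [align_auto()].
#' @return object of class `DistanceMatrix`: `labels`, integer matrix
#'   `ndiff`, numeric matrix `pdist`, integer matrix `comparable_sites`;
#'   all symmetric with zero diagonals.
#' @export
distance_matrix <- function(seqs, ...) {
  labels <- names(seqs)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("sequences must be named")
  n <- length(seqs)
  nd <- matrix(0L, n, n, dimnames = list(labels, labels))
  cs <- matrix(0L, n, n, dimnames = list(labels, labels))
  pd <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    cs[i, i] <- nchar(seqs[[i]])
    if (i < n) for (j in (i + 1L):n) {
      aln <- align_auto(seqs[[i]], seqs[[j]], ...)
      d <- p_distance(aln)
      nd[i, j] <- nd[j, i] <- d$ndiff
      cs[i, j] <- cs[j, i] <- d$comparable_sites
      pd[i, j] <- pd[j, i] <- d$p
    }
  }
  new_distance_matrix(labels, nd, pd, cs)
}

#' Assemble a distance matrix from precomputed values
#'
#' @param labels ordered labels.
#' @param ndiff,pdist,comparable_sites square matrices (symmetry and zero
#'   diagonals are validated).
#' @return a `DistanceMatrix`.
#' @export
new_distance_matrix <- function(labels, ndiff, pdist, comparable_sites) {
  for (m in list(ndiff, pdist, comparable_sites)) {
    stopifnot(nrow(m) == length(labels), ncol(m) == length(labels))
    if (!isTRUE(all.equal(m, t(m)))) stop("distance matrix not symmetric")
  }
  if (any(diag(pdist) != 0) || any(diag(ndiff) != 0))
    stop("distance matrix diagonal must be zero")
  structure(list(labels = labels, ndiff = ndiff, pdist = pdist,
                 comparable_sites = comparable_sites),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat("DistanceMatrix over", length(x$labels), "sequences\n")
  print(round(x$pdist, 4))
  invisible(x)
}

#' Mean p-distance between two groups
#'
#' Unweighted arithmetic mean over all `|X| x |Y|` cross pairs.
#'
#' @param matrix a `DistanceMatrix`.
#' @param groupX,groupY disjoint, non-empty label sets.
#' @return mean p-distance.
#' @export
group_mean_distance <- function(matrix, groupX, groupY) {
  if (!length(groupX) || !length(groupY)) stop("groups must be non-empty")
  if (length(intersect(groupX, groupY))) stop("groups overlap")
  miss <- setdiff(c(groupX, groupY), matrix$labels)
  if (length(miss)) stop("unknown labels: ", paste(miss, collapse = ", "))
  mean(matrix$pdist[groupX, groupY, drop = FALSE])
}

#' Fold difference between two divergences
#'
#' @param p_reference divergence of the reference (deeper) comparison.
#' @param p_focal divergence of the focal (shallower) comparison; must be
#'   positive.
#' @param digits decimals for reporting (half-away-from-zero); `NULL` for
#'   the raw ratio.
#' @return `p_reference / p_focal`.
#' @export
fold_difference <- function(p_reference, p_focal, digits = 1) {
  if (p_focal == 0) stop("undefined fold: focal divergence is zero")
  f <- p_reference / p_focal
  if (is.null(digits)) f else round_half_up(f, digits)
}

#' Calibration-ratio divergence-time estimate
#'
#' Scales a calibrated node age by the fold difference between the
#' calibrated (reference) divergence and the focal divergence: the focal
#' split is `fold` times shallower, so its age is the calibration age
#' divided by `fold`, with the half-width scaled identically (strictly
#' proportional error propagation).
#'
#' @param calibration numeric `c(point, half_width)` in mya.
#' @param fold positive fold difference (reference / focal).
#' @param basis text label of the marker the fold was measured on.
#' @param digits decimals for the reported estimate.
#' @return object of class `DivergenceEstimate` with unrounded
#'   `point`/`half_width` and rounded `point_reported`/
#'   `half_width_reported`.
#' @export
scale_divergence <- function(calibration, fold, basis = "", digits = 1) {
  if (!is.numeric(calibration) || length(calibration) != 2L)
    stop("calibration must be c(point, half_width) in mya")
  if (fold <= 0) stop("fold must be positive")
  point <- calibration[1] / fold
  hw <- calibration[2] / fold
  structure(list(
    point = point, half_width = hw,
    point_reported = round_half_up(point, digits),
    half_width_reported = round_half_up(hw, digits),
    calibration_point = calibration[1],
    calibration_half_width = calibration[2],
    fold = fold, basis = basis),
    class = "DivergenceEstimate")
}

#' @export
print.DivergenceEstimate <- function(x, ...) {
  cat("DivergenceEstimate", if (nzchar(x$basis)) paste0("(", x$basis, ")"),
      ": ", x$point_reported, " ± ", x$half_width_reported,
      " mya (calibration ", x$calibration_point, " ± ",
      x$calibration_half_width, " mya / fold ", x$fold, ")\n", sep = "")
  invisible(x)
}

#' Export a distance matrix as TSV or PHYLIP
#'
#' @param matrix a `DistanceMatrix`.
#' @param path output file.
#' @param format `"tsv"` (square, labeled, p-distances) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(matrix, path,
                                  format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(
      data.frame(label = matrix$labels, matrix$pdist, check.names = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(sprintf("%5d", length(matrix$labels)),
               vapply(seq_along(matrix$labels), function(i)
                 paste0(formatC(substr(matrix$labels[i], 1, 10),
                                width = -10),
                        paste(sprintf("%.6f", matrix$pdist[i, ]),
                              collapse = " ")),
                 character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
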