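## Barcode similarity by interval Jaccard matching.  Bars of one
## homology dimension are matched greedily in descending interval-Jaccard
## order (interval Jaccard = overlap length / union length on the alpha
## axis), each bar used at most once; the similarity S is the sum of
## matched Jaccards normalized by the larger bar count.  S is symmetric,
## lies in [0, 1], equals 1 for identical barcodes and 0 for barcodes
## with no overlapping bars.

#' @noRd
barcode_intervals <- function(barcode, dimension) {
  stopifnot(inherits(barcode, "barcode"))
  amax <- attr(barcode, "alpha_max_nm")
  b <- barcode[barcode$dimension == dimension, , drop = FALSE]
  cbind(birth = b$birth_nm, death = pmin(b$death_nm, amax))
}

#' Jaccard-based similarity of two barcodes
#'
#' @param b1,b2 `barcode` objects analyzed with the same alpha_max
#' @param dimension homology dimension: 0 (components) or 1 (holes)
#' @return similarity S in [0, 1]; two empty barcodes give 1, exactly
#'   one empty gives 0
#' @export
jaccard_barcodes <- function(b1, b2, dimension = 0L) {
  if (!identical(attr(b1, "alpha_max_nm"), attr(b2, "alpha_max_nm")))
    stopf("barcodes analyzed with different alpha_max (%g vs %g)",
          attr(b1, "alpha_max_nm"), attr(b2, "alpha_max_nm"))
  i1 <- barcode_intervals(b1, dimension)
  i2 <- barcode_intervals(b2, dimension)
  n1 <- nrow(i1); n2 <- nrow(i2)
  if (n1 == 0L && n2 == 0L) return(1)
  if (n1 == 0L || n2 == 0L) return(0)
  lo <- outer(i1[, 1L], i2[, 1L], pmax)
  hi <- outer(i1[, 2L], i2[, 2L], pmin)
  inter <- pmax(hi - lo, 0)
  uni <- outer(i1[, 2L] - i1[, 1L], i2[, 2L] - i2[, 1L], `+`) - inter
  jac <- ifelse(uni > 0, inter / uni,
                # two zero-length bars: identical position counts as 1
                as.numeric(outer(i1[, 1L], i2[, 1L], `==`) & inter == 0 &
                             outer(i1[, 2L], i2[, 2L], `==`)))
  used1 <- logical(n1); used2 <- logical(n2)
  ord <- order(-jac, rep(seq_len(n1), n2),
               rep(seq_len(n2), each = n1))
  total <- 0
  matched <- 0L
  for (k in ord) {
    if (jac[k] <= 0) break
    i <- (k - 1L) %% n1 + 1L
    j <- (k - 1L) %/% n1 + 1L
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    total <- total + jac[k]
    matched <- matched + 1L
    if (matched == min(n1, n2)) break
  }
  total / max(n1, n2)
}

#' First-generation similarity heatmap
#'
#' Pairwise barcode similarities of one labelling type: a symmetric
#' matrix with unit diagonal.
#'
#' @param barcodes list (optionally named) of `barcode` objects
#' @param dimension homology dimension, 0 or 1
#' @return a `similarity_heatmap` (generation 1)
#' @export
first_generation_heatmap <- function(barcodes, dimension = 0L) {
  k <- length(barcodes)
  if (k < 2L) stopf("need at least two barcodes for a heatmap")
  nm <- names(barcodes)
  if (is.null(nm)) nm <- paste0("sample", seq_len(k))
  S <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    S[i, j] <- S[j, i] <- jaccard_barcodes(barcodes[[i]], barcodes[[j]],
                                           dimension)
  }
  diag(S) <- vapply(barcodes, function(b)
    jaccard_barcodes(b, b, dimension), numeric(1))
  structure(list(values = S, generation = 1L, dimension = dimension),
            class = "similarity_heatmap")
}

#' Rectangular cross-label similarity block
#'
#' @param barcodes_a,barcodes_b lists of `barcode` objects
#' @param dimension homology dimension
#' @return matrix of similarities (rows: a, columns: b)
#' @export
cross_label_similarity <- function(barcodes_a, barcodes_b,
                                   dimension = 0L) {
  S <- matrix(NA_real_, length(barcodes_a), length(barcodes_b))
  for (i in seq_along(barcodes_a)) for (j in seq_along(barcodes_b))
    S[i, j] <- jaccard_barcodes(barcodes_a[[i]], barcodes_b[[j]],
                                dimension)
  S
}

#' Second-generation similarity heatmap
#'
#' Each cell is the mean of the corresponding first-generation block:
#' for a label against itself, the mean of the off-diagonal entries of
#' its square first-generation heatmap; for two different labels, the
#' mean of the full rectangular cross block.  Missing label pairs give
#' `NA`.
#'
#' @param gen1_maps named list of matrices; names are `"X|Y"` label
#'   pairs (one entry per unordered pair, plus `"X|X"` per label)
#' @param labels character vector of labels (row/column order)
#' @param dimension homology dimension the blocks were computed for
#' @return a `similarity_heatmap` (generation 2)
#' @export
second_generation_heatmap <- function(gen1_maps, labels,
                                      dimension = 0L) {
  k <- length(labels)
  S <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    key <- paste(labels[i], labels[j], sep = "|")
    alt <- paste(labels[j], labels[i], sep = "|")
    m <- gen1_maps[[key]]
    if (is.null(m)) m <- if (!is.null(gen1_maps[[alt]]))
      t(gen1_maps[[alt]])
    if (is.null(m)) next
    S[i, j] <- if (i == j) {
      if (nrow(m) > 1L) mean(m[row(m) != col(m)]) else m[1L, 1L]
    } else mean(m)
  }
  structure(list(values = S, generation = 2L, dimension = dimension),
            class = "similarity_heatmap")
}

#' Build first- and second-generation heatmaps from grouped barcodes
#'
#' @param barcodes_by_label named list; each element a list of
#'   `barcode` objects of one labelling type (e.g. one per nucleus)
#' @param dimension homology dimension, 0 (components) or 1 (holes)
#' @return list with `gen1` (named list of matrices keyed `"X|Y"`) and
#'   `gen2` (a `similarity_heatmap`)
#' @export
similarity_heatmaps <- function(barcodes_by_label, dimension = 0L) {
  labels <- names(barcodes_by_label)
  stopifnot(length(labels) >= 1L)
  gen1 <- list()
  for (i in seq_along(labels)) for (j in i:length(labels)) {
    key <- paste(labels[i], labels[j], sep = "|")
    gen1[[key]] <- if (i == j) {
      if (length(barcodes_by_label[[i]]) >= 2L)
        first_generation_heatmap(barcodes_by_label[[i]],
                                 dimension)$values
      else cross_label_similarity(barcodes_by_label[[i]],
                                  barcodes_by_label[[i]], dimension)
    } else cross_label_similarity(barcodes_by_label[[i]],
                                  barcodes_by_label[[j]], dimension)
  }
  list(gen1 = gen1,
       gen2 = second_generation_heatmap(gen1, labels, dimension))
}

#' @export
print.similarity_heatmap <- function(x, ...) {
  cat(sprintf("similarity heatmap (generation %d, dimension %d):\n",
              x$generation, x$dimension))
  print(round(x$values, 3))
  invisible(x)
}
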