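#' Pairwise percent nucleotide identity of two aligned sequences
#'
#' The identity statistic used throughout the 16S analysis: the number of
#' columns at which both sequences carry the identical (unambiguous)
#' nucleotide, divided by the number of aligned columns, where columns
#' gapped in *both* sequences ("shared indels") are excluded from the
#' denominator. Columns gapped in exactly one sequence count as aligned and
#' non-identical under the default convention.
#'
#' @param a,b Equal-length gapped residue strings (case-insensitive; `.` is
#'   treated as a gap like `-`).
#' @param count_single_gaps If `TRUE` (default) columns with a gap in exactly
#'   one sequence stay in the denominator; if `FALSE` every gap-containing
#'   column is excluded.
#' @param ambiguity_identical If `FALSE` (default) IUPAC ambiguity codes
#'   (anything other than A, C, G, T) never score as identical, even to the
#'   same code; set `TRUE` to count exact character matches of any residue.
#' @return A proportion in `[0, 1]`.
#' @examples
#' pairwise_pid("A-CGT", "AACGT")  # 4 identical of 5 counted columns
#' pairwise_pid("AC--G", "AC--G")  # shared-gap columns excluded -> 1
#' @export
pairwise_pid <- function(a, b, count_single_gaps = TRUE,
                         ambiguity_identical = FALSE) {
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  }
  ca <- str_to_codes(a)
  cb <- str_to_codes(b)
  pid_from_codes(ca, cb, count_single_gaps, ambiguity_identical)
}

# Encode residues as integers: gap = 0L, A/C/G/T = 1..4, anything else
# (ambiguity codes, N) = its character code + 4 so exact-character matches
# remain detectable.
str_to_codes <- function(s) {
  r <- utf8ToInt(toupper(s))
  out <- integer(length(r))
  out[r == utf8ToInt("-") | r == utf8ToInt(".")] <- 0L
  out[r == utf8ToInt("A")] <- 1L
  out[r == utf8ToInt("C")] <- 2L
  out[r == utf8ToInt("G")] <- 3L
  out[r == utf8ToInt("T")] <- 4L
  other <- out == 0L & r != utf8ToInt("-") & r != utf8ToInt(".")
  out[other] <- r[other] + 4L
  out
}

pid_from_codes <- function(ca, cb, count_single_gaps, ambiguity_identical) {
  both_gap <- ca == 0L & cb == 0L
  if (count_single_gaps) {
    counted <- !both_gap
  } else {
    counted <- ca != 0L & cb != 0L
  }
  denom <- sum(counted)
  if (denom == 0L) {
    stop("identity undefined: no counted columns (all shared gaps)",
         call. = FALSE)
  }
  if (ambiguity_identical) {
    ident <- counted & ca == cb & ca != 0L
  } else {
    ident <- counted & ca == cb & ca >= 1L & ca <= 4L
  }
  sum(ident) / denom
}

#' All-pairs identity matrix for an alignment
#'
#' Computes [pairwise_pid()] for every unordered pair of sequences in an
#' alignment and returns a symmetric matrix object with diagonal 1.
#'
#' @param aln A `gaoscope_alignment` (see [read_alignment()]) or any data
#'   frame with `id` and equal-length `seq` columns.
#' @inheritParams pairwise_pid
#' @return An object of class `pid_matrix`: a list with `ids` and the
#'   symmetric numeric matrix `values`. Use [tidy()] for a long pair table.
#' @export
pid_matrix <- function(aln, count_single_gaps = TRUE,
                       ambiguity_identical = FALSE) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  codes <- lapply(aln$seq, str_to_codes)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- tryCatch(
        pid_from_codes(codes[[i]], codes[[j]], count_single_gaps,
                       ambiguity_identical),
        error = function(e) {
          stop("identity undefined for pair (", aln$id[i], ", ", aln$id[j],
               "): ", conditionMessage(e), call. = FALSE)
        }
      )
      m[i, j] <- m[j, i] <- v
    }
  }
  dimnames(m) <- list(aln$id, aln$id)
  structure(list(ids = aln$id, values = m,
                 count_single_gaps = count_single_gaps,
                 ambiguity_identical = ambiguity_identical),
            class = "pid_matrix")
}

#' @export
print.pid_matrix <- function(x, ...) {
  cat("# PID matrix: ", length(x$ids), " sequences, ",
      choose(length(x$ids), 2L), " pairs\n", sep = "")
  off <- x$values[upper.tri(x$values)]
  cat("  identity range: ", sprintf("%.4f", min(off)), " - ",
      sprintf("%.4f", max(off)), "\n", sep = "")
  invisible(x)
}

#' @rdname pid_matrix
#' @param x A `pid_matrix`.
#' @param ... Unused.
#' @method tidy pid_matrix
#' @export
tidy.pid_matrix <- function(x, ...) {
  ids <- x$ids
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(id_a = ids[idx[, 1L]], id_b = ids[idx[, 2L]],
                 pid = x$values[idx])
}

#' Write a PID matrix as wide TSV
#' @param x A `pid_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pid_matrix <- function(x, path) {
  df <- tibble::as_tibble(x$values, rownames = "id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# Normalise a group table (id, group) and check it against matrix ids.
as_group_tbl <- function(groups) {
  if (!is.data.frame(groups) || !all(c("id", "group") %in% names(groups))) {
    stop("groups must be a data frame with columns 'id' and 'group'",
         call. = FALSE)
  }
  groups <- tibble::as_tibble(groups)[, c("id", "group")]
  if (anyDuplicated(groups$id)) {
    stop("each sequence id may carry at most one group label", call. = FALSE)
  }
  groups
}

#' Identity distribution between two labelled groups
#'
#' Collects all between-group (or within-group) pairwise identities from a
#' [pid_matrix()], the substrate of the violin-plot comparison of taxa.
#' Self-pairs are never included; within one group the `n(n-1)/2` unordered
#' pairs are used.
#'
#' @param x A `pid_matrix`.
#' @param groups Data frame with columns `id`, `group`; ids without a label
#'   are excluded from all group statistics.
#' @param group_a,group_b Group labels (may be equal for a within-group
#'   distribution).
#' @return An object of class `pni_distribution` with the raw `values` and
#'   summary statistics; see [tidy()] and [glance()].
#' @export
group_pni <- function(x, groups, group_a, group_b) {
  stopifnot(inherits(x, "pid_matrix"))
  groups <- as_group_tbl(groups)
  ids_a <- intersect(groups$id[groups$group == group_a], x$ids)
  ids_b <- intersect(groups$id[groups$group == group_b], x$ids)
  if (length(ids_a) == 0L) stop("unknown or empty group: ", group_a, call. = FALSE)
  if (length(ids_b) == 0L) stop("unknown or empty group: ", group_b, call. = FALSE)
  if (identical(group_a, group_b)) {
    if (length(ids_a) < 2L) {
      stop("within-group distribution needs >= 2 members in ", group_a,
           call. = FALSE)
    }
    sub <- x$values[ids_a, ids_a, drop = FALSE]
    values <- sub[upper.tri(sub)]
  } else {
    values <- as.vector(x$values[ids_a, ids_b, drop = FALSE])
  }
  structure(list(group_a = group_a, group_b = group_b, values = values,
                 n_pairs = length(values),
                 median = stats::median(values), mean = mean(values),
                 min = min(values), max = max(values)),
            class = "pni_distribution")
}

#' @export
print.pni_distribution <- function(x, ...) {
  cat("# PNI distribution: ", x$group_a, " vs ", x$group_b,
      " (", x$n_pairs, " pairs)\n", sep = "")
  cat(sprintf("  median %.4f  mean %.4f  range [%.4f, %.4f]\n",
              x$median, x$mean, x$min, x$max))
  invisible(x)
}

#' @rdname group_pni
#' @param ... Unused.
#' @method tidy pni_distribution
#' @export
tidy.pni_distribution <- function(x, ...) {
  tibble::tibble(group_a = x$group_a, group_b = x$group_b, pni = x$values)
}

#' @rdname group_pni
#' @method glance pni_distribution
#' @export
glance.pni_distribution <- function(x, ...) {
  tibble::tibble(group_a = x$group_a, group_b = x$group_b,
                 n_pairs = x$n_pairs, median = x$median, mean = x$mean,
                 min = x$min, max = x$max)
}

#' Median inter-family identity (MIF) within a reference order
#'
#' For every unordered pair of distinct families the mean between-family
#' identity is computed; the MIF statistic is the median of those means and
#' the band is their min/max. This provides a data-driven yardstick for how
#' different two families within one order typically are.
#'
#' @param x A `pid_matrix`.
#' @param families Data frame with columns `id`, `group` giving the family
#'   label of each sequence.
#' @param order_members Optional character vector of family labels to
#'   restrict to (e.g. the families of one order); default: all labels.
#' @return An object of class `mif_statistic`: `mif`, `band_low`,
#'   `band_high`, the mean-of-means (`mean_of_means`, the alternative
#'   central-value reading) and a `family_pairs` tibble.
#' @export
median_inter_family <- function(x, families, order_members = NULL) {
  stopifnot(inherits(x, "pid_matrix"))
  families <- as_group_tbl(families)
  if (!is.null(order_members)) {
    families <- families[families$group %in% order_members, ]
  }
  fams <- sort(unique(families$group))
  fams <- fams[vapply(fams, function(f)
    length(intersect(families$id[families$group == f], x$ids)) >= 1L,
    logical(1))]
  if (length(fams) < 2L) {
    stop("need at least 2 families with members in the matrix", call. = FALSE)
  }
  pairs <- utils::combn(fams, 2L)
  means <- apply(pairs, 2L, function(p) {
    group_pni(x, families, p[1L], p[2L])$mean
  })
  fp <- tibble::tibble(family_a = pairs[1L, ], family_b = pairs[2L, ],
                       mean_pni = means)
  structure(list(mif = stats::median(means), band_low = min(means),
                 band_high = max(means), mean_of_means = mean(means),
                 family_pairs = fp),
            class = "mif_statistic")
}

#' @export
print.mif_statistic <- function(x, ...) {
  cat(sprintf("# MIF %.4f (band [%.4f, %.4f], mean-of-means %.4f) over %d family pairs\n",
              x$mif, x$band_low, x$band_high, x$mean_of_means,
              nrow(x$family_pairs)))
  invisible(x)
}

#' @rdname median_inter_family
#' @param ... Unused.
#' @method tidy mif_statistic
#' @export
tidy.mif_statistic <- function(x, ...) x$family_pairs

#' @rdname median_inter_family
#' @method glance mif_statistic
#' @export
glance.mif_statistic <- function(x, ...) {
  tibble::tibble(mif = x$mif, band_low = x$band_low, band_high = x$band_high,
                 mean_of_means = x$mean_of_means,
                 n_family_pairs = nrow(x$family_pairs))
}

#' Minimal-inclusion identity thresholds for taxonomic ranks
#'
#' Constructor for the rank thresholds used by [place_group()]. The defaults
#' are conventional 16S minimal inclusion thresholds from the rank-threshold
#' literature; override them to taste.
#'
#' @param genus,family,order Identity proportions with
#'   `1 > genus > family > order > 0`.
#' @return A named list of class `rank_thresholds`.
#' @export
rank_thresholds <- function(genus = 0.945, family = 0.865, order = 0.82) {
  if (!(1 > genus && genus > family && family > order && order > 0)) {
    stop("thresholds must satisfy 1 > genus > family > order > 0",
         call. = FALSE)
  }
  structure(list(genus = genus, family = family, order = order),
            class = "rank_thresholds")
}

#' Threshold-based taxonomic rank placement of one group against another
#'
#' Places a query group relative to a reference group from the median of
#' their between-group identity distribution: at or above the genus
#' threshold the groups are consistent with one genus, between family and
#' genus thresholds with one family, between order and family thresholds
#' with one order, and below the order threshold the relationship is beyond
#' the order level. The fraction of pairs above each threshold is reported
#' alongside but does not drive the call.
#'
#' @param x A `pid_matrix`.
#' @param groups Data frame with columns `id`, `group`.
#' @param query,reference Group labels.
#' @param thresholds A [rank_thresholds()] object.
#' @return An object of class `placement_call`; see [glance()].
#' @export
place_group <- function(x, groups, query, reference,
                        thresholds = rank_thresholds()) {
  stopifnot(inherits(thresholds, "rank_thresholds"))
  dist <- group_pni(x, groups, query, reference)
  med <- dist$median
  rank_call <- if (med >= thresholds$genus) "same_genus"
  else if (med >= thresholds$family) "same_family"
  else if (med >= thresholds$order) "same_order"
  else "beyond_order"
  fraction_above <- vapply(thresholds, function(t) mean(dist$values >= t),
                           numeric(1))
  structure(list(query = query, reference = reference,
                 median_pni = med, fraction_above = fraction_above,
                 rank_call = rank_call, thresholds = thresholds,
                 distribution = dist),
            class = "placement_call")
}

#' @export
print.placement_call <- function(x, ...) {
  cat("# Placement: ", x$query, " vs ", x$reference, " -> ", x$rank_call,
      "\n", sep = "")
  cat(sprintf("  median PNI %.4f over %d pairs; fraction >= thresholds: g %.2f, f %.2f, o %.2f\n",
              x$median_pni, x$distribution$n_pairs,
              x$fraction_above[["genus"]], x$fraction_above[["family"]],
              x$fraction_above[["order"]]))
  invisible(x)
}

#' @rdname place_group
#' @param ... Unused.
#' @method glance placement_call
#' @export
glance.placement_call <- function(x, ...) {
  tibble::tibble(query = x$query, reference = x$reference,
                 median_pni = x$median_pni, rank_call = x$rank_call,
                 n_pairs = x$distribution$n_pairs,
                 fraction_above_genus = x$fraction_above[["genus"]],
                 fraction_above_family = x$fraction_above[["family"]],
                 fraction_above_order = x$fraction_above[["order"]])
}

#' Neighbor-joining tree from a PID matrix
#'
#' Builds an unrooted neighbor-joining tree on distances `d = 1 - PID` for
#' quick clade visualisation. Negative branch lengths (an NJ artefact) are
#' clamped at zero.
#'
#' @param x A `pid_matrix` with at least 4 taxa.
#' @return An [ape::phylo] object (serialise with [ape::write.tree()]).
#' @export
build_nj_tree <- function(x) {
  stopifnot(inherits(x, "pid_matrix"))
  if (length(x$ids) < 4L) stop("need >= 4 taxa for an NJ tree", call. = FALSE)
  d <- stats::as.dist(1 - x$values)
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
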