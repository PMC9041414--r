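#' Cut a genome into consecutive non-overlapping fragments
#'
#' Fragment-based ANI works on fixed-length chunks of the query genome.
#' Fragments never span contigs; a trailing remainder shorter than
#' `fragment_length` is discarded, as are fragments that are mostly `N`.
#'
#' @param genome A FASTA path or a data frame with `id` and `seq` columns
#'   (one row per contig).
#' @param fragment_length Fragment size in bp (>= 100; default 1020).
#' @return A tibble with `fragment_index`, `contig`, `start`, `end` (1-based
#'   inclusive, contig coordinates) and `seq`.
#' @export
fragment_genome <- function(genome, fragment_length = 1020L) {
  genome <- as_seq_tbl(genome)
  fragment_length <- as.integer(fragment_length)
  if (fragment_length < 100L) stop("fragment_length must be >= 100", call. = FALSE)
  if (max(nchar(genome$seq)) < fragment_length) {
    stop("genome shorter than one fragment (", fragment_length, " bp)",
         call. = FALSE)
  }
  frags <- purrr::map2_dfr(genome$id, genome$seq, function(contig, s) {
    n <- nchar(s) %/% fragment_length
    if (n == 0L) return(tibble::tibble())
    start <- (seq_len(n) - 1L) * fragment_length + 1L
    end <- start + fragment_length - 1L
    tibble::tibble(contig = contig, start = start, end = end,
                   seq = substring(s, start, end))
  })
  n_count <- stringr::str_count(frags$seq, "N")
  frags <- frags[n_count <= nchar(frags$seq) / 2, ]
  frags$fragment_index <- seq_len(nrow(frags))
  frags[, c("fragment_index", "contig", "start", "end", "seq")]
}

# Concatenate contigs with an N spacer; returns the string plus per-contig
# global offsets so interval arithmetic can move between coordinate systems.
concat_genome <- function(genome, spacer = 50L) {
  genome <- as_seq_tbl(genome)
  lens <- nchar(genome$seq)
  glob_start <- cumsum(c(0L, utils::head(lens + spacer, -1L))) + 1L
  list(seq = paste(genome$seq, collapse = strrep("N", spacer)),
       offsets = tibble::tibble(contig = genome$id, glob_start = glob_start,
                                glob_end = glob_start + lens - 1L))
}

# Reverse complement of a plain character string.
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Seed stage: exact k-mers sampled along each fragment vote for a diagonal
# on one strand of the subject; the modal diagonal per fragment wins.
seed_diagonals <- function(frags, subject_chr, k, seed_stride) {
  L <- nchar(frags$seq[1L])
  offsets <- unique(c(seq(1L, L - k + 1L, by = seed_stride), L - k + 1L))
  seed_df <- tidyr::expand_grid(fragment_index = frags$fragment_index,
                                offset = offsets)
  seed_df$seed <- substring(frags$seq[match(seed_df$fragment_index,
                                            frags$fragment_index)],
                            seed_df$offset, seed_df$offset + k - 1L)
  seed_df <- seed_df[grepl("^[ACGT]+$", seed_df$seed), ]
  if (nrow(seed_df) == 0L) return(tibble::tibble())
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_df$seed))
  hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject_chr))
  n_hits <- S4Vectors::elementNROWS(hits)
  if (sum(n_hits) == 0L) return(tibble::tibble())
  all_starts <- IRanges::start(unlist(hits, use.names = FALSE))
  hit_df <- tibble::tibble(
    fragment_index = rep(seed_df$fragment_index, n_hits),
    diag = all_starts - rep(seed_df$offset, n_hits)
  )
  # modal diagonal per fragment, ties to the lowest diagonal
  counts <- dplyr::count(hit_df, .data$fragment_index, .data$diag)
  counts <- dplyr::arrange(counts, .data$fragment_index, -.data$n, .data$diag)
  out <- counts[!duplicated(counts$fragment_index), ]
  tibble::tibble(fragment_index = out$fragment_index, diag = out$diag,
                 votes = out$n)
}

# Identity of the ungapped diagonal placement (N never matches).
ungapped_identity <- function(frag_seq, subject_chr, diag) {
  L <- nchar(frag_seq)
  rf <- charToRaw(frag_seq)
  rs <- charToRaw(substring(subject_chr, diag + 1L, diag + L))
  sum(rf == rs & rf != charToRaw("N")) / L
}

# Extension stage. The ungapped placement along the winning diagonal is
# scored first; the affine gapped aligner (global in the fragment, local in
# a banded window) only runs when the ungapped identity falls below
# `gap_trigger` or the diagonal leaves the subject — i.e. when indels are
# plausible. Divergences at or below typical species-level distances stay
# on the fast path.
align_candidates <- function(frags, subject_chr, cands, band,
                             gap_trigger = 0.75) {
  if (nrow(cands) == 0L) return(empty_hits())
  L <- nchar(frags$seq[1L])
  slen <- nchar(subject_chr)
  seqs <- frags$seq[match(cands$fragment_index, frags$fragment_index)]
  in_bounds <- cands$diag >= 0L & cands$diag + L <= slen
  ident_ug <- rep(NA_real_, nrow(cands))
  ident_ug[in_bounds] <- vapply(which(in_bounds), function(i) {
    ungapped_identity(seqs[i], subject_chr, cands$diag[i])
  }, numeric(1))
  fast <- in_bounds & ident_ug >= gap_trigger
  out <- tibble::tibble(
    fragment_index = cands$fragment_index,
    subject_start = cands$diag + 1L,
    subject_end = cands$diag + L,
    identity = ident_ug,
    query_coverage = 1,
    votes = cands$votes,
    orientation = NA_character_
  )
  if (any(!fast)) {
    idx <- which(!fast)
    win_start <- pmax(1L, cands$diag[idx] + 1L - band)
    win_end <- pmin(slen, cands$diag[idx] + L + band)
    pats <- Biostrings::DNAStringSet(seqs[idx])
    subs <- Biostrings::DNAStringSet(substring(subject_chr, win_start,
                                               win_end))
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(pats, subs, type = "global-local",
                                         substitutionMatrix = mat,
                                         gapOpening = 6, gapExtension = 2)
    aln_len <- Biostrings::nchar(aln)
    sub_rng <- aln@subject@range
    out$subject_start[idx] <- win_start + IRanges::start(sub_rng) - 1L
    out$subject_end[idx] <- win_start + IRanges::end(sub_rng) - 1L
    out$identity[idx] <- Biostrings::nmatch(aln) / aln_len
    out$query_coverage[idx] <- pmin(1, aln_len / L)
  }
  out
}

empty_hits <- function() {
  tibble::tibble(fragment_index = integer(), subject_start = integer(),
                 subject_end = integer(), identity = numeric(),
                 query_coverage = numeric(), votes = integer(),
                 orientation = character())
}

#' Map genome fragments onto a subject genome
#'
#' Seed-and-extend mapping of each fragment against both strands of a
#' subject genome: exact k-mer seeds vote for a diagonal, the winning
#' diagonal defines a banded candidate window, and the fragment is globally
#' aligned against that window. Only the best hit per fragment is kept, and
#' only if its query coverage and identity clear the reporting floors; a
#' fragment with no surviving hit is simply absent from the result.
#'
#' @param frags Fragment tibble from [fragment_genome()].
#' @param subject Subject genome: FASTA path or `id`/`seq` data frame.
#'   Multi-contig subjects are concatenated with an `N` spacer; reported
#'   subject intervals are in that concatenated coordinate system.
#' @param k Seed length (default 16).
#' @param seed_stride Spacing of sampled seeds along the fragment.
#' @param band_frac Half-width of the alignment window beyond the fragment,
#'   as a fraction of fragment length.
#' @param min_cov,min_ident Reporting floors for query coverage and identity.
#' @return A tibble of fragment hits with `fragment_index`, subject
#'   interval, `identity`, `query_coverage`, `votes`, `orientation`.
#' @export
map_fragments <- function(frags, subject, k = 16L, seed_stride = 24L,
                          band_frac = 0.05, min_cov = 0.7, min_ident = 0.5) {
  cat_subj <- concat_genome(subject)
  if (nrow(frags) == 0L) return(empty_hits())
  L <- nchar(frags$seq[1L])
  band <- max(5L, as.integer(ceiling(band_frac * L)))
  slen <- nchar(cat_subj$seq)
  res <- list()
  for (orient in c("forward", "reverse")) {
    s <- if (orient == "forward") cat_subj$seq else revcomp_chr(cat_subj$seq)
    cands <- seed_diagonals(frags, s, k, seed_stride)
    hits <- align_candidates(frags, s, cands, band)
    if (nrow(hits) > 0L) {
      if (orient == "reverse") {
        tmp_start <- slen - hits$subject_end + 1L
        hits$subject_end <- slen - hits$subject_start + 1L
        hits$subject_start <- tmp_start
      }
      hits$orientation <- orient
      res[[orient]] <- hits
    }
  }
  hits <- dplyr::bind_rows(res)
  if (nrow(hits) == 0L) return(empty_hits())
  hits <- dplyr::ungroup(dplyr::slice_max(
    dplyr::group_by(hits, .data$fragment_index),
    order_by = .data$identity, n = 1L, with_ties = FALSE))
  hits <- hits[hits$query_coverage >= min_cov & hits$identity >= min_ident, ]
  dplyr::arrange(hits, .data$fragment_index)
}

# Global (concatenated) coordinates of each fragment of a genome.
fragment_global_coords <- function(frags, genome) {
  off <- concat_genome(genome)$offsets
  g0 <- off$glob_start[match(frags$contig, off$contig)]
  tibble::tibble(fragment_index = frags$fragment_index,
                 glob_start = g0 + frags$start - 1L,
                 glob_end = g0 + frags$end - 1L)
}

# Which subject fragment contains each hit's midpoint (NA if none).
hit_target_fragment <- function(hits, subj_coords) {
  if (nrow(hits) == 0L) return(integer())
  mid <- (hits$subject_start + hits$subject_end) %/% 2L
  idx <- findInterval(mid, subj_coords$glob_start)
  target <- rep(NA_integer_, length(mid))
  ok <- idx >= 1L
  ok[ok] <- mid[ok] <= subj_coords$glob_end[idx[ok]]
  target[ok] <- subj_coords$fragment_index[idx[ok]]
  target
}

#' Fragment-based average nucleotide identity of two genomes
#'
#' Both genomes are fragmented, each fragment set is mapped onto the other
#' genome with [map_fragments()], and the ANI is the mean identity over
#' reciprocal-best fragment pairs, expressed as a percentage. The result is
#' undefined (`NA`) when fewer than `min_fraction_used` of all fragments
#' participate in a reciprocal pair — the signature of unrelated genomes.
#' The conventional species boundary is ~95% ANI; see
#' [classify_species_boundary()].
#'
#' @param genome_a,genome_b FASTA paths or `id`/`seq` data frames.
#' @param fragment_length Fragment size in bp (default 1020).
#' @param k Seed k-mer length (default 16).
#' @param min_fraction_used Floor on the fraction of fragments retained for
#'   the ANI to be defined (default 0.2).
#' @param name_a,name_b Optional genome labels (default: first contig id).
#' @param ... Further arguments passed to [map_fragments()].
#' @return An object of class `ani_result`; see [tidy()] and [glance()].
#' @export
compute_ani <- function(genome_a, genome_b, fragment_length = 1020L,
                        k = 16L, min_fraction_used = 0.2,
                        name_a = NULL, name_b = NULL, ...) {
  ga <- as_seq_tbl(genome_a)
  gb <- as_seq_tbl(genome_b)
  name_a <- name_a %||% ga$id[1L]
  name_b <- name_b %||% gb$id[1L]
  fa <- fragment_genome(ga, fragment_length)
  fb <- fragment_genome(gb, fragment_length)
  hits_ab <- map_fragments(fa, gb, k = k, ...)
  hits_ba <- map_fragments(fb, ga, k = k, ...)
  coords_a <- fragment_global_coords(fa, ga)
  coords_b <- fragment_global_coords(fb, gb)
  hits_ab$target <- hit_target_fragment(hits_ab, coords_b)
  hits_ba$target <- hit_target_fragment(hits_ba, coords_a)
  # reciprocal-best: A-fragment i hits inside B-fragment j and vice versa
  best_ab <- stats::setNames(hits_ab$target, hits_ab$fragment_index)
  best_ba <- stats::setNames(hits_ba$target, hits_ba$fragment_index)
  recip_a <- !is.na(hits_ab$target) &
    !is.na(best_ba[as.character(hits_ab$target)]) &
    best_ba[as.character(hits_ab$target)] == hits_ab$fragment_index
  recip_b <- !is.na(hits_ba$target) &
    !is.na(best_ab[as.character(hits_ba$target)]) &
    best_ab[as.character(hits_ba$target)] == hits_ba$fragment_index
  used <- dplyr::bind_rows(
    dplyr::mutate(hits_ab[recip_a, ], direction = "a_to_b"),
    dplyr::mutate(hits_ba[recip_b, ], direction = "b_to_a")
  )
  n_total <- nrow(fa) + nrow(fb)
  n_used <- nrow(used)
  ani <- if (n_total == 0L || n_used / n_total < min_fraction_used) NA_real_
  else 100 * mean(used$identity)
  structure(list(genome_a = name_a, genome_b = name_b, ani = ani,
                 n_fragments_total = n_total, n_fragments_used = n_used,
                 min_fraction_used = min_fraction_used, hits = used),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  val <- if (is.na(x$ani)) "undefined" else sprintf("%.2f%%", x$ani)
  cat("# ANI ", x$genome_a, " vs ", x$genome_b, ": ", val, " (",
      x$n_fragments_used, "/", x$n_fragments_total, " fragments)\n", sep = "")
  invisible(x)
}

#' @rdname compute_ani
#' @param x An `ani_result`.
#' @method tidy ani_result
#' @export
tidy.ani_result <- function(x, ...) x$hits

#' @rdname compute_ani
#' @method glance ani_result
#' @export
glance.ani_result <- function(x, ...) {
  tibble::tibble(genome_a = x$genome_a, genome_b = x$genome_b, ani = x$ani,
                 n_fragments_total = x$n_fragments_total,
                 n_fragments_used = x$n_fragments_used,
                 fraction_used = x$n_fragments_used /
                   max(1L, x$n_fragments_total))
}

#' Species-boundary interpretation of an ANI value
#'
#' Genome pairs below the ANI species cutoff (conventionally 95%) are
#' interpreted as distinct species; an undefined ANI (too few alignable
#' fragments) yields `"undefined"`.
#'
#' @param result An `ani_result` from [compute_ani()], or a bare numeric ANI
#'   percentage.
#' @param cutoff Species boundary in percent (default 95).
#' @return One of `"same_species"`, `"distinct_species"`, `"undefined"`.
#' @export
classify_species_boundary <- function(result, cutoff = 95) {
  ani <- if (inherits(result, "ani_result")) result$ani else as.numeric(result)
  if (is.na(ani)) return("undefined")
  if (ani < cutoff) "distinct_species" else "same_species"
}
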