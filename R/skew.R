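#' Windowed and cumulative GC skew of a genome
#'
#' Computes `(G - C) / (G + C)` in consecutive non-overlapping windows plus
#' the running (cumulative) sum. On circular bacterial chromosomes the
#' leading strand is G-rich, so the cumulative curve decreases along one
#' replichore and increases along the other; its extrema locate the
#' replication origin and terminus.
#'
#' @param genome A FASTA path, an `id`/`seq` data frame (first record used),
#'   or a bare sequence string.
#' @param window Window size in bp (>= 100; default 5000). The final partial
#'   window is retained.
#' @param circular Is the replicon circular? Carried as metadata.
#' @return A tibble of class `skew_profile` with `window_index`, `start`,
#'   `end`, `midpoint`, `skew`, `cumulative`, and attributes `genome_id`,
#'   `window`, `genome_length`, `circular`. Windows with no G or C have
#'   skew 0.
#' @export
windowed_gc_skew <- function(genome, window = 5000L, circular = TRUE) {
  window <- as.integer(window)
  if (window < 100L) stop("window must be >= 100 bp", call. = FALSE)
  if (is.character(genome) && length(genome) == 1L && !file.exists(genome) &&
      grepl("^[ACGTUNacgtun-]+$", genome)) {
    genome <- tibble::tibble(id = "genome", seq = toupper(chartr("Uu", "Tt", genome)))
  }
  genome <- as_seq_tbl(genome)
  s <- genome$seq[1L]
  len <- nchar(s)
  if (len < 2L * window) {
    stop("genome (", len, " bp) shorter than two windows", call. = FALSE)
  }
  r <- charToRaw(s)
  is_g <- r == charToRaw("G")
  is_c <- r == charToRaw("C")
  win_id <- (seq_len(len) - 1L) %/% window + 1L
  g <- tapply(is_g, win_id, sum)
  c_ <- tapply(is_c, win_id, sum)
  gc <- as.numeric(g + c_)
  skew <- ifelse(gc == 0, 0, (as.numeric(g) - as.numeric(c_)) / gc)
  n_win <- length(skew)
  start <- (seq_len(n_win) - 1L) * window + 1L
  end <- pmin(start + window - 1L, len)
  out <- tibble::tibble(
    window_index = seq_len(n_win), start = start, end = end,
    midpoint = (start + end) / 2,
    skew = as.numeric(skew), cumulative = cumsum(as.numeric(skew))
  )
  attr(out, "genome_id") <- genome$id[1L]
  attr(out, "window") <- window
  attr(out, "genome_length") <- len
  attr(out, "circular") <- circular
  class(out) <- c("skew_profile", class(out))
  out
}

#' Predict replication origin and terminus from a skew profile
#'
#' Under the G-rich-leading-strand convention the cumulative GC-skew curve
#' attains its global minimum at the origin and its global maximum at the
#' terminus; positions are reported as window midpoints, ties broken at the
#' lowest position. For circular replicons the cumulative curve is first
#' detrended (its net per-revolution drift removed) so the prediction does
#' not depend on where the circle was linearised. Set `ori_at = "max"` to
#' invert the convention.
#'
#' @param profile A `skew_profile` from [windowed_gc_skew()].
#' @param ori_at `"min"` (default) or `"max"`: which cumulative extremum is
#'   the origin.
#' @return An object of class `ori_ter_prediction` with `ori_position`,
#'   `ter_position` (bp, window midpoints), `amplitude` (cumulative max -
#'   min) and `no_signal` (`TRUE` when the cumulative curve is flat).
#' @export
predict_ori_ter <- function(profile, ori_at = c("min", "max")) {
  stopifnot(inherits(profile, "skew_profile"))
  ori_at <- match.arg(ori_at)
  cum <- profile$cumulative
  if (isTRUE(attr(profile, "circular"))) {
    # remove the net per-revolution drift so the curve closes and the
    # extrema do not depend on where the circle was linearised
    cum <- cum - profile$window_index * mean(profile$skew)
  }
  i_min <- which.min(cum)   # which.min/max take the first (lowest) position
  i_max <- which.max(cum)
  amplitude <- cum[i_max] - cum[i_min]
  if (ori_at == "min") {
    ori_i <- i_min; ter_i <- i_max
  } else {
    ori_i <- i_max; ter_i <- i_min
  }
  structure(list(
    genome_id = attr(profile, "genome_id"),
    ori_position = profile$midpoint[ori_i],
    ter_position = profile$midpoint[ter_i],
    ori_window = ori_i, ter_window = ter_i,
    amplitude = amplitude,
    no_signal = amplitude == 0,
    window = attr(profile, "window"),
    genome_length = attr(profile, "genome_length")
  ), class = "ori_ter_prediction")
}

#' @export
print.ori_ter_prediction <- function(x, ...) {
  if (x$no_signal) {
    cat("# ori/ter prediction: no skew signal (flat cumulative curve)\n")
  } else {
    cat(sprintf("# ori/ter prediction: ori %.0f bp, ter %.0f bp (amplitude %.3f)\n",
                x$ori_position, x$ter_position, x$amplitude))
  }
  invisible(x)
}

#' @rdname predict_ori_ter
#' @param x An `ori_ter_prediction`.
#' @param ... Unused.
#' @method glance ori_ter_prediction
#' @export
glance.ori_ter_prediction <- function(x, ...) {
  tibble::tibble(genome_id = x$genome_id, ori_position = x$ori_position,
                 ter_position = x$ter_position, amplitude = x$amplitude,
                 no_signal = x$no_signal, window = x$window,
                 genome_length = x$genome_length)
}

# Minimal distance between two positions on a circle of given length.
circular_distance <- function(a, b, length) {
  d <- abs(a - b) %% length
  pmin(d, length - d)
}

#' Distance from the predicted origin to the dnaA gene
#'
#' The chromosomal replication initiator gene dnaA typically sits at or very
#' near the origin; its circular distance to the predicted origin is a
#' sanity check on the skew-based prediction.
#'
#' @param pred An `ori_ter_prediction`.
#' @param annotations Annotation tibble containing exactly one row whose
#'   `gene_symbol` matches `symbol` (case-insensitive).
#' @param genome_length Replicon length in bp (default: taken from `pred`).
#' @param symbol Gene symbol of the initiator gene (default `"dnaA"`).
#' @return Minimal circular distance in bp between the predicted origin and
#'   the gene midpoint.
#' @export
dnaa_proximity <- function(pred, annotations, genome_length = NULL,
                           symbol = "dnaA") {
  stopifnot(inherits(pred, "ori_ter_prediction"))
  genome_length <- genome_length %||% pred$genome_length
  ann <- tibble::as_tibble(annotations)
  hit <- ann[tolower(ann$gene_symbol) == tolower(symbol), ]
  if (nrow(hit) == 0L) {
    stop("no annotation row with gene_symbol '", symbol, "'", call. = FALSE)
  }
  if (nrow(hit) > 1L) {
    stop("multiple '", symbol, "' rows: ",
         paste(hit$gene_id, collapse = ", "), call. = FALSE)
  }
  if (is.na(hit$start) || is.na(hit$end)) {
    stop("'", symbol, "' row lacks coordinates", call. = FALSE)
  }
  mid <- (hit$start + hit$end) / 2
  circular_distance(pred$ori_position, mid, genome_length)
}

#' Bin a per-base coverage track into fixed windows
#'
#' Mean depth per non-overlapping window; the final window may be partial
#' and its mean is taken over the bases it actually contains. The exact
#' per-window sums are returned as `total_depth`, so depth is conserved:
#' `sum(total_depth) == sum(depth)` exactly.
#'
#' @param track A numeric vector of per-base depths, or a data frame with
#'   columns `pos` and `depth` (see [read_coverage_track()]).
#' @param window Window size in bp (default 5000).
#' @return A tibble with `window_index`, `start`, `end`, `n_bases`,
#'   `total_depth` (exact per-window sum) and `mean_depth`.
#' @export
bin_coverage <- function(track, window = 5000L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  depth <- if (is.data.frame(track)) {
    track <- track[order(track$pos), ]
    track$depth
  } else as.numeric(track)
  if (length(depth) == 0L) stop("empty coverage track", call. = FALSE)
  if (any(depth < 0)) stop("negative depths in coverage track", call. = FALSE)
  len <- length(depth)
  win_id <- (seq_len(len) - 1L) %/% window + 1L
  sums <- as.numeric(tapply(depth, win_id, sum))
  n_bases <- as.integer(tapply(depth, win_id, length))
  n_win <- length(sums)
  start <- (seq_len(n_win) - 1L) * window + 1L
  # total_depth carries the exact per-window sum, so depth conservation
  # (sum over windows == sum over bases) holds without round-off
  tibble::tibble(window_index = seq_len(n_win), start = start,
                 end = pmin(start + window - 1L, len),
                 n_bases = n_bases, total_depth = sums,
                 mean_depth = sums / n_bases)
}
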