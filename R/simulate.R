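# Run code with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Expected identity of two sequences under the Jukes-Cantor model
#'
#' Closed form for the probability that two sites separated by a total path
#' divergence of `d` expected substitutions/site carry the same nucleotide:
#' `1/4 + 3/4 * exp(-4 d / 3)`.
#'
#' @param d Expected substitutions per site along the whole path separating
#'   the two sequences.
#' @return Expected proportion of identical sites.
#' @export
jc_expected_identity <- function(d) 0.25 + 0.75 * exp(-4 * d / 3)

#' Path divergence that yields a target Jukes-Cantor identity
#' @param identity Target expected identity in (0.25, 1].
#' @return Expected substitutions per site (inverse of
#'   [jc_expected_identity()]).
#' @export
jc_divergence_for_identity <- function(identity) {
  stopifnot(identity > 0.25, identity <= 1)
  -3 / 4 * log((identity - 0.25) / 0.75)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

# One Jukes-Cantor branch: each site substitutes independently with
# probability 3/4 (1 - exp(-4 d / 3)), uniformly to one of the other bases.
evolve_jc <- function(bases, d) {
  p_sub <- 3 / 4 * (1 - exp(-4 * d / 3))
  hit <- stats::runif(length(bases)) < p_sub
  if (any(hit)) {
    alphabet <- c("A", "C", "G", "T")
    cur <- bases[hit]
    pick <- vapply(cur, function(b) sample(setdiff(alphabet, b), 1L),
                   character(1))
    bases[hit] <- pick
  }
  bases
}

#' Simulate a clade-structured 16S-like alignment with known divergences
#'
#' Evolves a uniform random root sequence under Jukes-Cantor along a
#' star-of-stars tree: each clade ancestor sits `(d_b - d_w)/2` from the
#' root and each member `d_w/2` from its ancestor, so that the total path
#' divergence is `d_w` within a clade and `d_b` between clades. Gap columns
#' may be planted afterwards by masking alignment columns: shared gaps mask
#' the same columns in every member of clade 1 (a shared indel for
#' within-clade pairs), unshared gaps mask one random sequence each.
#'
#' @param n_clades,members_per_clade Shape of the star-of-stars tree.
#' @param d_w,d_b Within/between-clade expected substitutions per site
#'   (`d_b >= d_w >= 0`).
#' @param root_length Alignment length in nt (default 1500, full-length 16S).
#' @param shared_gap_columns,unshared_gap_columns Number of planted gap
#'   columns of each kind.
#' @param seed Optional integer seed; fixed seeds give byte-identical output.
#' @return A list with `alignment` (a `gaoscope_alignment` tibble), `groups`
#'   (tibble `id`, `group`) and `truth` (divergences, expected identities
#'   from [jc_expected_identity()], seed).
#' @export
simulate_clade_alignment <- function(n_clades = 2L, members_per_clade = 4L,
                                     d_w = 0.02, d_b = 0.30,
                                     root_length = 1500L,
                                     shared_gap_columns = 0L,
                                     unshared_gap_columns = 0L,
                                     seed = NULL) {
  if (!(d_b >= d_w && d_w >= 0)) {
    stop("divergences must satisfy d_b >= d_w >= 0", call. = FALSE)
  }
  with_local_seed(seed, {
    root <- random_dna(root_length)
    seqs <- list()
    groups <- list()
    for (cl in seq_len(n_clades)) {
      anc <- evolve_jc(root, (d_b - d_w) / 2)
      label <- sprintf("clade%02d", cl)
      for (m in seq_len(members_per_clade)) {
        id <- sprintf("%s_seq%02d", label, m)
        seqs[[id]] <- evolve_jc(anc, d_w / 2)
        groups[[id]] <- label
      }
    }
    mat <- do.call(rbind, seqs)
    if (shared_gap_columns > 0L) {
      cols <- sample(root_length, shared_gap_columns)
      clade1 <- startsWith(rownames(mat), "clade01")
      mat[clade1, cols] <- "-"
    }
    if (unshared_gap_columns > 0L) {
      for (i in seq_len(unshared_gap_columns)) {
        mat[sample(nrow(mat), 1L), sample(root_length, 1L)] <- "-"
      }
    }
    aln <- as_alignment(tibble::tibble(
      id = rownames(mat), description = "",
      seq = apply(mat, 1L, paste, collapse = "")))
    list(
      alignment = aln,
      groups = tibble::tibble(id = rownames(mat),
                              group = unlist(groups[rownames(mat)])),
      truth = list(d_w = d_w, d_b = d_b,
                   expected_identity_within = jc_expected_identity(d_w),
                   expected_identity_between = jc_expected_identity(d_b),
                   n_clades = n_clades,
                   members_per_clade = members_per_clade,
                   root_length = root_length,
                   shared_gap_columns = shared_gap_columns,
                   unshared_gap_columns = unshared_gap_columns, seed = seed)
    )
  })
}

#' Simulate a genome pair at a controlled substitution divergence
#'
#' The second genome is the first with i.i.d. substitutions at per-site rate
#' `p`, always to a different base, optionally split into contigs; the ANI
#' engine should recover `100 * (1 - p)` on such pairs.
#'
#' @param length Genome length in bp.
#' @param p Per-site substitution rate in `[0, 0.3]`.
#' @param n_contigs Number of (near-)equal contigs to split each genome into.
#' @param gc GC content of the ancestral genome.
#' @param seed Optional integer seed.
#' @return A list with `genome_a`, `genome_b` (`id`/`seq` tibbles) and
#'   `truth` (`p`, realised `n_substitutions`, `length`, seed).
#' @export
simulate_genome_pair <- function(length = 200000L, p = 0.05, n_contigs = 1L,
                                 gc = 0.5, seed = NULL) {
  stopifnot(p >= 0, p <= 0.3)
  with_local_seed(seed, {
    a <- random_dna(length, gc)
    hit <- stats::runif(length) < p
    b <- a
    if (any(hit)) {
      alphabet <- c("A", "C", "G", "T")
      b[hit] <- vapply(a[hit], function(x) sample(setdiff(alphabet, x), 1L),
                       character(1))
    }
    split_contigs <- function(bases, prefix) {
      cuts <- floor(seq(0L, length(bases), length.out = n_contigs + 1L))
      tibble::tibble(
        id = sprintf("%s_contig%02d", prefix, seq_len(n_contigs)),
        seq = vapply(seq_len(n_contigs), function(i) {
          paste(bases[(cuts[i] + 1L):cuts[i + 1L]], collapse = "")
        }, character(1))
      )
    }
    list(genome_a = split_contigs(a, "genomeA"),
         genome_b = split_contigs(b, "genomeB"),
         truth = list(p = p, n_substitutions = sum(hit), length = length,
                      n_contigs = n_contigs, seed = seed))
  })
}

#' Simulate a circular genome with planted replichore GC bias
#'
#' Bases on the ori-to-ter arc are drawn with `P(G) - P(C) = strength`, and
#' with the sign flipped on the complementary arc, emulating the G-rich
#' leading strand of a single bidirectionally replicating origin. A dnaA
#' annotation row is planted at the origin.
#'
#' @param length Genome length in bp.
#' @param ori,ter Planted origin and terminus positions (bp, `ori != ter`).
#' @param strength GC-skew strength in `(0, 0.3]`; must not exceed `gc`.
#' @param gc Overall GC content.
#' @param seed Optional integer seed.
#' @return A list with `genome` (`id`/`seq` tibble), `annotations` (one
#'   dnaA row at the origin) and `truth` (planted positions, the expected
#'   per-window skew `strength / gc`, seed).
#' @export
simulate_skew_genome <- function(length = 1e6, ori = 150000L, ter = 650000L,
                                 strength = 0.2, gc = 0.5, seed = NULL) {
  stopifnot(strength > 0, strength <= 0.3, strength <= gc, ori != ter)
  length <- as.integer(length)
  with_local_seed(seed, {
    pos <- seq_len(length)
    on_arc <- ((pos - ori) %% length) < ((ter - ori) %% length)
    draw <- function(n, delta) {
      p <- c(A = (1 - gc) / 2, C = gc / 2 - delta / 2, G = gc / 2 + delta / 2,
             T = (1 - gc) / 2)
      sample(names(p), n, replace = TRUE, prob = p)
    }
    bases <- character(length)
    bases[on_arc] <- draw(sum(on_arc), strength)
    bases[!on_arc] <- draw(sum(!on_arc), -strength)
    ann <- tibble::tibble(
      genome_id = "sim_skew", gene_id = "SIM_dnaA_0001",
      gene_symbol = "dnaA",
      product = "chromosomal replication initiator protein DnaA",
      ko_id = "K02313",
      start = as.integer(ori), end = as.integer(min(ori + 1349L, length)),
      strand = "+")
    list(genome = tibble::tibble(id = "sim_skew",
                                 seq = paste(bases, collapse = "")),
         annotations = ann,
         truth = list(ori = ori, ter = ter, strength = strength, gc = gc,
                      expected_window_skew = strength / gc,
                      length = length, seed = seed))
  })
}

# A satisfying KO set for one definition subtree (first-alternative choice).
satisfying_kos <- function(node) {
  switch(node$type,
         ko = node$id,
         true = character(0),
         optional = character(0),
         or = satisfying_kos(node$children[[1L]]),
         unique(unlist(lapply(node$children, satisfying_kos))))
}

status_from_counts <- function(missing, genes, override) {
  if (override) "-"
  else if (genes == 0L) "-"
  else if (missing == 0L) "C"
  else if (missing <= 2L) "+"
  else "?"
}

# Choose which blocks to leave unsatisfied so that exactly `target` blocks
# evaluate false under the union of the kept blocks' KO sets.
plan_block_subset <- function(module, target, max_combos = 200L) {
  n <- length(module$blocks)
  if (target > n) return(NULL)
  if (target == 0L) {
    kos <- unique(unlist(lapply(module$blocks, satisfying_kos)))
    if (count_missing_kos_ok(module, kos, 0L)) return(kos) else return(NULL)
  }
  combos <- utils::combn(n, target, simplify = FALSE)
  if (length(combos) > max_combos) combos <- combos[seq_len(max_combos)]
  for (miss in combos) {
    keep <- setdiff(seq_len(n), miss)
    kos <- unique(unlist(lapply(module$blocks[keep], satisfying_kos)))
    if (count_missing_kos_ok(module, kos, target)) return(kos)
  }
  NULL
}

count_missing_kos_ok <- function(module, kos, target) {
  miss <- sum(!vapply(module$blocks, eval_node, logical(1), kos = kos))
  miss == target
}

#' Simulate annotation tables with planted module-completeness states
#'
#' Emits per-genome KO-bearing annotation rows so that each (genome, module)
#' combination has exactly the planted number of unsatisfied blocks, and
#' optionally hides a fraction of the present KOs behind empty KO cells with
#' a rescuable product string (with matching rescue rules generated), to
#' exercise annotation rescue end to end.
#'
#' @param modules Module table (see [read_module_table()]) or list of
#'   `module_definition`s.
#' @param plan Data frame with columns `genome_id`, `module_id`,
#'   `missing_blocks` (target unsatisfied blocks after rescue).
#' @param hide_for_rescue Fraction in `[0, 1]` of emitted KOs per (genome,
#'   module) whose KO id is hidden (rescuable via product string).
#' @param seed Optional integer seed.
#' @return A list with `annotations` (all genomes, one table),
#'   `rescue_rules`, and `truth`: a tibble per (genome, module) with the
#'   planted `missing_blocks`, `status_pre` / `status_post` rescue, gene
#'   counts and hidden KO ids.
#' @export
simulate_annotation_tables <- function(modules, plan, hide_for_rescue = 0,
                                       seed = NULL) {
  stopifnot(hide_for_rescue >= 0, hide_for_rescue <= 1)
  mods <- parse_module_table(modules)
  names(mods) <- vapply(mods, `[[`, character(1), "module_id")
  plan <- tibble::as_tibble(plan)
  need <- c("genome_id", "module_id", "missing_blocks")
  stopifnot(all(need %in% names(plan)))
  with_local_seed(seed, {
    ann_rows <- list()
    rules <- list()
    truth <- list()
    gene_counter <- 0L
    for (r in seq_len(nrow(plan))) {
      g <- plan$genome_id[r]
      mid <- plan$module_id[r]
      target <- as.integer(plan$missing_blocks[r])
      mod <- mods[[mid]]
      if (is.null(mod)) stop("plan references unknown module ", mid, call. = FALSE)
      kos <- plan_block_subset(mod, target)
      if (is.null(kos)) {
        stop("unachievable plan for (", g, ", ", mid, "): cannot leave ",
             target, " block(s) unsatisfied", call. = FALSE)
      }
      n_hide <- floor(hide_for_rescue * length(kos))
      hidden <- if (n_hide > 0L) sample(kos, n_hide) else character(0)
      rows <- purrr::map_dfr(kos, function(ko) {
        gene_counter <<- gene_counter + 1L
        hid <- ko %in% hidden
        tibble::tibble(
          genome_id = g,
          gene_id = sprintf("%s_%05d", toupper(g), gene_counter),
          gene_symbol = "",
          product = if (hid) paste0("rescuable ", ko, " homolog (", mid, ")")
          else paste0("annotated ", ko, " protein"),
          ko_id = if (hid) "" else ko,
          start = NA_integer_, end = NA_integer_, strand = "")
      })
      ann_rows[[r]] <- rows
      if (length(hidden) > 0L) {
        rules[[r]] <- tibble::tibble(
          match_on = "product_regex",
          pattern = paste0("rescuable ", hidden, " homolog \\(", mid, "\\)"),
          target_ko = hidden)
      }
      visible <- setdiff(kos, hidden)
      miss_pre <- sum(!vapply(mod$blocks, eval_node, logical(1),
                              kos = visible))
      override_pre <- length(mod$diagnostic_kos) > 0L &&
        !any(mod$diagnostic_kos %in% visible)
      override_post <- length(mod$diagnostic_kos) > 0L &&
        !any(mod$diagnostic_kos %in% kos)
      truth[[r]] <- tibble::tibble(
        genome_id = g, module_id = mid,
        missing_blocks = target,
        n_kos = length(kos), n_hidden = length(hidden),
        hidden_kos = paste(sort(hidden), collapse = ","),
        status_pre = status_from_counts(miss_pre, length(visible),
                                        override_pre),
        status_post = status_from_counts(target, length(kos), override_post)
      )
    }
    rules <- dplyr::bind_rows(rules)
    if (nrow(rules) > 0L) rules <- dplyr::distinct(rules)
    list(annotations = dplyr::bind_rows(ann_rows),
         rescue_rules = if (nrow(rules) > 0L) rules else
           tibble::tibble(match_on = character(), pattern = character(),
                          target_ko = character()),
         truth = dplyr::bind_rows(truth))
  })
}
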