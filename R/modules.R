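#' Parse a KEGG-module DEFINITION expression
#'
#' KEGG module definitions are boolean expressions over KO identifiers:
#' space separates sequential blocks (all required, AND), comma separates
#' alternatives (OR), `+` joins subunits of a complex (AND within an
#' alternative), a leading `-` marks a non-essential component (ignored for
#' completeness), parentheses nest, and the gap marker `--` denotes an
#' undefined reaction step that counts as satisfied.
#'
#' @param text Definition string, e.g. `"K00001 (K00002,K00003) K00004+K00005"`.
#' @param module_id,name Optional metadata carried on the result.
#' @param diagnostic_kos Optional character vector of diagnostic KO ids for
#'   the absence override (see [classify_status()]).
#' @return An object of class `module_definition` with fields `module_id`,
#'   `name`, `definition`, `tree`, `blocks` (list of top-level required
#'   block subtrees), `diagnostic_kos` and `ko_universe`.
#' @export
parse_module_definition <- function(text, module_id = NA_character_,
                                    name = "", diagnostic_kos = character()) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("empty module definition", call. = FALSE)
  }
  toks <- tokenize_definition(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- parse_seq(st)
  if (st$pos <= length(st$toks)) {
    stop("parse error in module definition at token ", st$pos, " ('",
         st$toks[st$pos], "')", call. = FALSE)
  }
  blocks <- if (identical(tree$type, "seq")) tree$children else list(tree)
  blocks <- blocks[!vapply(blocks, function(b) identical(b$type, "optional"),
                           logical(1))]
  structure(list(module_id = module_id, name = name, definition = text,
                 tree = tree, blocks = blocks,
                 diagnostic_kos = diagnostic_kos,
                 ko_universe = collect_kos(tree)),
            class = "module_definition")
}

tokenize_definition <- function(text) {
  rest <- gsub("[[:space:]]", "", gsub("--|\\(|\\)|,|\\+|-|[A-Za-z0-9_.]+",
                                       "", text))
  if (nzchar(rest)) {
    stop("unexpected character(s) in module definition: '", rest, "'",
         call. = FALSE)
  }
  # scan left to right, keeping whitespace as an explicit separator token
  toks2 <- character(0)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[[:space:]]", ch)) {
      if (length(toks2) && toks2[length(toks2)] != " ") toks2 <- c(toks2, " ")
      i <- i + 1L
    } else if (substr(text, i, i + 1L) == "--") {
      toks2 <- c(toks2, "--"); i <- i + 2L
    } else if (ch %in% c("(", ")", ",", "+", "-")) {
      toks2 <- c(toks2, ch); i <- i + 1L
    } else {
      len <- attr(regexpr("^[A-Za-z0-9_.]+", substr(text, i, n)),
                  "match.length")
      toks2 <- c(toks2, substr(text, i, i + len - 1L))
      i <- i + len
    }
  }
  # trim boundary spaces
  while (length(toks2) && toks2[1L] == " ") toks2 <- toks2[-1L]
  while (length(toks2) && toks2[length(toks2)] == " ") {
    toks2 <- toks2[-length(toks2)]
  }
  toks2
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA
advance <- function(st) { st$pos <- st$pos + 1L; invisible(NULL) }

# seq := or_term (SPACE or_term)*
parse_seq <- function(st) {
  children <- list(parse_or(st))
  while (identical(peek(st), " ")) {
    advance(st)
    children <- c(children, list(parse_or(st)))
  }
  if (length(children) == 1L) children[[1L]]
  else list(type = "seq", children = children)
}

# or := cplx (COMMA cplx)*
parse_or <- function(st) {
  children <- list(parse_cplx(st))
  while (identical(peek(st), ",")) {
    advance(st)
    children <- c(children, list(parse_cplx(st)))
  }
  if (length(children) == 1L) children[[1L]]
  else list(type = "or", children = children)
}

# cplx := item ((PLUS|MINUS) item)*  with MINUS marking the next item optional
parse_cplx <- function(st) {
  children <- list(parse_item(st))
  while (!is.na(peek(st)) && peek(st) %in% c("+", "-")) {
    op <- peek(st)
    advance(st)
    item <- parse_item(st)
    if (op == "-") item <- list(type = "optional", child = item)
    children <- c(children, list(item))
  }
  if (length(children) == 1L) children[[1L]]
  else list(type = "cand", children = children)
}

# item := "--" | "-" item | ID | "(" seq ")"
parse_item <- function(st) {
  tok <- peek(st)
  if (is.na(tok)) stop("unexpected end of module definition", call. = FALSE)
  if (tok == "--") { advance(st); return(list(type = "true")) }
  if (tok == "-") {
    advance(st)
    return(list(type = "optional", child = parse_item(st)))
  }
  if (tok == "(") {
    advance(st)
    inner <- parse_seq(st)
    if (!identical(peek(st), ")")) {
      stop("unbalanced parentheses in module definition at token ", st$pos,
           call. = FALSE)
    }
    advance(st)
    return(inner)
  }
  if (tok %in% c(")", ",", "+", " ")) {
    stop("parse error in module definition at token ", st$pos, " ('", tok,
         "')", call. = FALSE)
  }
  advance(st)
  list(type = "ko", id = tok)
}

collect_kos <- function(node) {
  switch(node$type,
         ko = node$id,
         true = character(0),
         optional = collect_kos(node$child),
         unique(unlist(lapply(node$children, collect_kos))))
}

# Evaluate a definition subtree against a KO set. Optional components and
# gap markers are always satisfied.
eval_node <- function(node, kos) {
  switch(node$type,
         ko = node$id %in% kos,
         true = TRUE,
         optional = TRUE,
         or = any(vapply(node$children, eval_node, logical(1), kos = kos)),
         all(vapply(node$children, eval_node, logical(1), kos = kos)))
}

#' Serialise a parsed module definition back to DEFINITION syntax
#' @param module A `module_definition` (or a bare parse tree).
#' @return A definition string that reparses to an identical tree.
#' @export
unparse_module_definition <- function(module) {
  tree <- if (inherits(module, "module_definition")) module$tree else module
  render_node(tree, 0L)
}

# precedence: seq 1 < or 2 < cand 3 < atom 4
render_node <- function(node, ctx) {
  prec <- switch(node$type, seq = 1L, or = 2L, cand = 3L, 4L)
  out <- switch(node$type,
    ko = node$id,
    true = "--",
    optional = paste0("-", render_node(node$child, 4L)),
    seq = paste(vapply(node$children, render_node, character(1), ctx = 1L),
                collapse = " "),
    or = paste(vapply(node$children, render_node, character(1), ctx = 2L),
               collapse = ","),
    cand = {
      parts <- vapply(node$children, function(ch) {
        if (identical(ch$type, "optional")) {
          paste0("-", render_node(ch$child, 4L))
        } else {
          render_node(ch, 3L)
        }
      }, character(1))
      # '-' renders its own separator; join remaining with '+'
      s <- parts[1L]
      for (p in parts[-1L]) {
        s <- if (startsWith(p, "-")) paste0(s, p) else paste0(s, "+", p)
      }
      s
    }
  )
  if (prec < ctx) paste0("(", out, ")") else out
}

#' @export
print.module_definition <- function(x, ...) {
  cat("# KEGG module ", x$module_id, if (nzchar(x$name)) paste0(" (", x$name, ")"),
      ": ", length(x$blocks), " block(s), ", length(x$ko_universe),
      " KO(s)\n", sep = "")
  invisible(x)
}

#' Build a per-genome KO profile from an annotation table
#'
#' @param annotations Annotation tibble (see [read_annotation_table()]).
#' @param genome_id Genome to extract; defaults to the single genome present.
#' @return An object of class `ko_profile`: `genome_id`, the KO set `kos`,
#'   `gene_count_by_ko` (named integer, paralogs counted) and
#'   `provenance_by_ko` (named character, `primary_annotation` or `rescued`).
#' @export
ko_profile <- function(annotations, genome_id = NULL) {
  ann <- tibble::as_tibble(annotations)
  if (is.null(genome_id)) {
    gs <- setdiff(unique(ann$genome_id), "")
    if (length(gs) > 1L) {
      stop("multiple genomes in table; pass genome_id", call. = FALSE)
    }
    genome_id <- if (length(gs) == 1L) gs else "genome"
  } else {
    ann <- ann[ann$genome_id == genome_id, ]
  }
  with_ko <- ann[nzchar(ann$ko_id), ]
  counts <- table(with_ko$ko_id)
  kos <- names(counts)
  structure(list(genome_id = genome_id, kos = kos,
                 gene_count_by_ko = stats::setNames(as.integer(counts), kos),
                 provenance_by_ko = stats::setNames(
                   rep("primary_annotation", length(kos)), kos)),
            class = "ko_profile")
}

#' @export
print.ko_profile <- function(x, ...) {
  n_res <- sum(x$provenance_by_ko == "rescued")
  cat("# KO profile ", x$genome_id, ": ", length(x$kos), " KOs (",
      n_res, " rescued), ", sum(x$gene_count_by_ko), " genes\n", sep = "")
  invisible(x)
}

#' Rescue KOs missed by the primary annotation source
#'
#' Cross-references a genome's annotation rows against rescue rules: when a
#' rule's pattern matches at least one row, the rule's target KO is added to
#' the profile with provenance `rescued`. This mirrors manual recovery of
#' false negatives (e.g. a malyl-CoA thioesterase or glycogen debranching
#' enzyme present in the gene-product annotation but missing a KO
#' assignment). The operation never removes KOs and is idempotent.
#'
#' @param profile A [ko_profile()].
#' @param annotations Annotation tibble for the same genome.
#' @param rules Data frame with columns `match_on` (one of `gene_symbol`,
#'   `product_regex`, `gene_id`), `pattern` and `target_ko`.
#' @return The updated `ko_profile`.
#' @export
apply_rescue <- function(profile, annotations, rules) {
  stopifnot(inherits(profile, "ko_profile"))
  ann <- tibble::as_tibble(annotations)
  if ("genome_id" %in% names(ann) && any(nzchar(ann$genome_id))) {
    ann <- ann[ann$genome_id %in% c(profile$genome_id, ""), ]
  }
  rules <- tibble::as_tibble(rules)
  need <- c("match_on", "pattern", "target_ko")
  if (!all(need %in% names(rules))) {
    stop("rescue rules need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- !grepl("^K[0-9]{5}$", rules$target_ko)
  if (any(bad)) {
    stop("malformed rescue target KO(s): ",
         paste(unique(rules$target_ko[bad]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(rules))) {
    hit <- switch(rules$match_on[i],
      gene_symbol = tolower(ann$gene_symbol) == tolower(rules$pattern[i]),
      product_regex = grepl(rules$pattern[i], ann$product, ignore.case = TRUE),
      gene_id = ann$gene_id == rules$pattern[i],
      stop("unknown match_on: ", rules$match_on[i], call. = FALSE))
    n_hit <- sum(hit)
    ko <- rules$target_ko[i]
    if (n_hit > 0L && !(ko %in% profile$kos)) {
      profile$kos <- c(profile$kos, ko)
      profile$gene_count_by_ko[ko] <- n_hit
      profile$provenance_by_ko[ko] <- "rescued"
    }
  }
  profile
}

#' Count unsatisfied blocks of a module for a KO profile
#'
#' @param module A `module_definition`.
#' @param profile A `ko_profile` (or a bare character vector of KO ids).
#' @return Integer number of top-level required blocks whose boolean
#'   expression is false given the profile's KO set.
#' @export
count_missing_blocks <- function(module, profile) {
  stopifnot(inherits(module, "module_definition"))
  kos <- if (inherits(profile, "ko_profile")) profile$kos else
    as.character(profile)
  sum(!vapply(module$blocks, eval_node, logical(1), kos = kos))
}

#' Four-level completeness status of a module in a genome
#'
#' Applies the status scheme used for pathway reporting:
#' \itemize{
#'   \item `-` (absent): no genes of the module detected, or — the
#'     diagnostic-gene override — none of the module's diagnostic KOs is
#'     present even though shared enzymes are (e.g. a glyoxylate cycle
#'     lacking isocitrate lyase, whose remaining enzymes all belong to the
#'     TCA cycle);
#'   \item `C` (complete): no missing blocks;
#'   \item `+` (largely intact): no more than 2 missing blocks;
#'   \item `?` (incomplete): more than 2 missing blocks.
#' }
#'
#' @param module A `module_definition`.
#' @param profile A `ko_profile`.
#' @param manually_confirmed Metadata flag for statuses confirmed by manual
#'   review of multiple annotation sources (rendered bold in publication
#'   tables); not used in classification.
#' @return A one-row tibble of class `completeness_call` with `module_id`,
#'   `genome_id`, `status`, `missing_blocks`, `genes_detected`,
#'   `rescued_kos`, `override_applied`, `manually_confirmed` and the
#'   rendered `cell` (`"status | n"`).
#' @export
classify_status <- function(module, profile, manually_confirmed = FALSE) {
  stopifnot(inherits(module, "module_definition"),
            inherits(profile, "ko_profile"))
  present <- intersect(module$ko_universe, profile$kos)
  genes_detected <- sum(profile$gene_count_by_ko[present])
  missing <- count_missing_blocks(module, profile)
  override <- length(module$diagnostic_kos) > 0L &&
    !any(module$diagnostic_kos %in% profile$kos)
  status <- if (override) "-"
  else if (genes_detected == 0L) "-"
  else if (missing == 0L) "C"
  else if (missing <= 2L) "+"
  else "?"
  rescued <- intersect(present,
                       names(profile$provenance_by_ko)[
                         profile$provenance_by_ko == "rescued"])
  out <- tibble::tibble(
    module_id = module$module_id, genome_id = profile$genome_id,
    status = status, missing_blocks = as.integer(missing),
    genes_detected = as.integer(genes_detected),
    rescued_kos = paste(rescued, collapse = ","),
    override_applied = override,
    manually_confirmed = manually_confirmed,
    cell = paste(status, genes_detected, sep = " | ")
  )
  class(out) <- c("completeness_call", class(out))
  out
}

# Parse the rows of a module table into module_definition objects.
parse_module_table <- function(modules) {
  if (inherits(modules, "module_definition")) return(list(modules))
  if (is.list(modules) && !is.data.frame(modules) &&
      all(vapply(modules, inherits, logical(1), "module_definition"))) {
    return(modules)
  }
  stopifnot(is.data.frame(modules))
  diag <- if ("diagnostic_kos" %in% names(modules)) modules$diagnostic_kos
  else vector("list", nrow(modules))
  purrr::pmap(list(modules$definition, modules$module_id,
                   dplyr::coalesce(modules$name, ""), diag),
              function(def, id, nm, dk) {
                parse_module_definition(def, module_id = id, name = nm,
                                        diagnostic_kos = dk %||% character())
              })
}

#' Completeness calls for every module x genome combination
#'
#' @param modules A module table (see [read_module_table()]), a list of
#'   `module_definition`s, or a single `module_definition`.
#' @param profiles A list of [ko_profile()]s, or a multi-genome annotation
#'   tibble (profiles are then built per `genome_id`).
#' @param rescue_rules Optional rescue-rule table applied to every profile
#'   (needs `annotations` to be the tibble input).
#' @return A tibble with one `completeness_call` row per (module, genome).
#' @export
completeness_matrix <- function(modules, profiles, rescue_rules = NULL) {
  mods <- parse_module_table(modules)
  if (is.data.frame(profiles)) {
    ann <- tibble::as_tibble(profiles)
    genomes <- unique(ann$genome_id)
    profs <- lapply(genomes, function(g) {
      p <- ko_profile(ann, g)
      if (!is.null(rescue_rules)) p <- apply_rescue(p, ann, rescue_rules)
      p
    })
  } else {
    profs <- profiles
    if (inherits(profs, "ko_profile")) profs <- list(profs)
  }
  if (length(mods) == 0L || length(profs) == 0L) {
    stop("need at least one module and one genome profile", call. = FALSE)
  }
  out <- purrr::map_dfr(mods, function(m) {
    purrr::map_dfr(profs, function(p) classify_status(m, p))
  })
  tibble::as_tibble(out)
}

#' Render completeness calls as a wide module-by-genome table
#'
#' @param calls Long tibble from [completeness_matrix()].
#' @param path Optional TSV output path.
#' @return A wide tibble with one row per module and one `"status | n"`
#'   cell per genome.
#' @export
render_completeness <- function(calls, path = NULL) {
  wide <- tidyr::pivot_wider(
    calls[, c("module_id", "genome_id", "cell")],
    names_from = "genome_id", values_from = "cell")
  if (!is.null(path)) readr::write_tsv(wide, path, progress = FALSE)
  wide
}
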