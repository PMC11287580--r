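#' Read a hierarchical diagnosis lexicon
#'
#' A small terminology with SNOMED-style parent/child structure. TSV columns:
#' `concept_id`, `preferred_term`, `synonyms` (pipe-separated, may be empty),
#' `parent_ids` (pipe-separated, may be empty). The parent graph must be
#' acyclic and every parent must resolve within the lexicon.
#'
#' @param path TSV path; defaults to the packaged mini-terminology.
#' @return an object of class `diagnosis_lexicon` with elements `concepts`
#'   (list keyed by concept_id) and `term_index` (named vector, normalized
#'   term -> concept_id).
#' @export
read_diagnosis_lexicon <- function(path = shieldtext_file("diagnoses.tsv")) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#", fill = TRUE)
  need <- c("concept_id", "preferred_term", "synonyms", "parent_ids")
  if (!all(need %in% names(df)))
    stop("diagnosis lexicon must have columns: ", paste(need, collapse = ", "))
  split_pipe <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
  }
  concepts <- lapply(seq_len(nrow(df)), function(i) {
    list(concept_id = df$concept_id[i],
         preferred_term = df$preferred_term[i],
         synonyms = split_pipe(df$synonyms[i]),
         parent_ids = split_pipe(df$parent_ids[i]))
  })
  names(concepts) <- df$concept_id
  if (anyDuplicated(names(concepts)))
    stop("duplicate concept_id in lexicon")
  for (cn in concepts) {
    missing <- setdiff(cn$parent_ids, names(concepts))
    if (length(missing))
      stop("concept ", cn$concept_id, " has unresolved parent(s): ",
           paste(missing, collapse = ", "))
  }
  terms <- unlist(unname(lapply(concepts, function(cn)
    stats::setNames(rep(cn$concept_id, 1 + length(cn$synonyms)),
                    normalize_term(c(cn$preferred_term, cn$synonyms))))))
  terms <- terms[nzchar(names(terms))]
  dup <- names(terms)[duplicated(names(terms))]
  clash <- unique(dup[vapply(dup, function(d)
    length(unique(terms[names(terms) == d])) > 1, logical(1))])
  if (length(clash))
    stop("normalized term(s) claimed by two concepts: ",
         paste(clash, collapse = ", "))
  lex <- structure(list(concepts = concepts,
                        term_index = terms[!duplicated(names(terms))]),
                   class = "diagnosis_lexicon")
  # reject cycles up front so ancestors() never loops
  for (cid in names(concepts)) ancestors(cid, lex)
  lex
}

#' @export
print.diagnosis_lexicon <- function(x, ...) {
  cat("<diagnosis_lexicon>", length(x$concepts), "concepts,",
      length(x$term_index), "indexed terms\n")
  invisible(x)
}

#' Transitive ancestors of a concept
#'
#' Closure over `parent_ids`, excluding the concept itself. Errors if the
#' parent graph contains a cycle.
#'
#' @param concept a concept list or a concept_id string.
#' @param lexicon a [read_diagnosis_lexicon()] object.
#' @return character vector of ancestor concept_ids.
#' @export
ancestors <- function(concept, lexicon) {
  cid <- if (is.list(concept)) concept$concept_id else concept
  if (is.null(lexicon$concepts[[cid]])) stop("unknown concept: ", cid)
  seen <- character()
  frontier <- lexicon$concepts[[cid]]$parent_ids
  steps <- 0L
  while (length(frontier)) {
    steps <- steps + 1L
    if (steps > length(lexicon$concepts) + 1L)
      stop("cycle detected in parent graph at concept ", cid)
    new <- setdiff(frontier, seen)
    if (cid %in% new) stop("cycle detected in parent graph at concept ", cid)
    seen <- union(seen, new)
    frontier <- unique(unlist(lapply(new, function(p)
      lexicon$concepts[[p]]$parent_ids)))
  }
  seen
}

#' Tag a free-text diagnosis item with lexicon concepts
#'
#' Exact match of the whole normalized item first; otherwise the longest
#' contiguous token-subsequence matches, longest-match-wins, scanning left to
#' right without overlap. Returns an empty list when nothing matches.
#'
#' @param item free-text diagnosis line.
#' @param lexicon a [read_diagnosis_lexicon()] object.
#' @return list of concept lists (possibly empty).
#' @export
tag_diagnosis <- function(item, lexicon) {
  stopifnot(nzchar(item))
  norm <- normalize_term(item)
  if (!nzchar(norm)) return(list())
  idx <- lexicon$term_index
  hit <- idx[norm]
  if (!is.na(hit)) return(list(lexicon$concepts[[unname(hit)]]))
  toks <- strsplit(norm, " ", fixed = TRUE)[[1]]
  n <- length(toks)
  found <- character()
  i <- 1L
  while (i <= n) {
    best <- NULL
    best_len <- 0L
    for (j in n:i) {
      key <- paste(toks[i:j], collapse = " ")
      hit <- idx[key]
      if (!is.na(hit)) { best <- unname(hit); best_len <- j - i + 1L; break }
    }
    if (!is.null(best)) {
      found <- c(found, best)
      i <- i + best_len
    } else i <- i + 1L
  }
  lapply(unique(found), function(cid) lexicon$concepts[[cid]])
}

#' Read a comorbidity category map
#'
#' TSV columns `category`, `root_concept_id`: a category is flagged when a
#' tagged concept equals, or descends from, one of its root concepts.
#'
#' @param path TSV path; defaults to the packaged map.
#' @param lexicon lexicon used to validate the roots.
#' @return named list: category -> character vector of root concept_ids.
#' @export
read_category_map <- function(path = shieldtext_file("categories.tsv"),
                              lexicon = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!all(c("category", "root_concept_id") %in% names(df)))
    stop("category map must have columns category, root_concept_id")
  cmap <- split(df$root_concept_id, df$category)
  if (!is.null(lexicon)) {
    missing <- setdiff(unlist(cmap), names(lexicon$concepts))
    if (length(missing))
      stop("category root(s) absent from lexicon: ",
           paste(missing, collapse = ", "))
  }
  cmap
}

#' Roll tagged concepts up to a comorbidity profile
#'
#' A category is flagged iff some tagged concept equals, or has among its
#' ancestors, a root concept of that category. All diagnoses are treated as
#' current. Evidence records the matched concept ids (and source letter id
#' when supplied) for every flagged category.
#'
#' @param concepts list of concept lists (from [tag_diagnosis()]).
#' @param category_map from [read_category_map()].
#' @param lexicon the diagnosis lexicon.
#' @param source_id optional letter id recorded in the evidence.
#' @return object of class `comorbidity_profile`: named logical vector
#'   `flags` plus `evidence` (list per flagged category).
#' @export
build_comorbidity_profile <- function(concepts, category_map, lexicon,
                                      source_id = NA_character_) {
  cats <- names(category_map)
  flags <- stats::setNames(rep(FALSE, length(cats)), cats)
  evidence <- stats::setNames(vector("list", length(cats)), cats)
  for (cn in concepts) {
    reach <- c(cn$concept_id, ancestors(cn$concept_id, lexicon))
    for (cat in cats) {
      if (any(category_map[[cat]] %in% reach)) {
        flags[[cat]] <- TRUE
        evidence[[cat]] <- c(evidence[[cat]],
                             list(list(concept_id = cn$concept_id,
                                       source = source_id)))
      }
    }
  }
  structure(list(flags = flags, evidence = evidence[flags]),
            class = "comorbidity_profile")
}

#' Merge comorbidity profiles (union of flags and evidence)
#'
#' @param ... `comorbidity_profile` objects over the same category set.
#' @return a merged `comorbidity_profile`.
#' @export
merge_profiles <- function(...) {
  profs <- list(...)
  stopifnot(length(profs) >= 1)
  flags <- profs[[1]]$flags
  evidence <- profs[[1]]$evidence
  for (p in profs[-1]) {
    flags <- flags | p$flags
    for (cat in names(p$evidence))
      evidence[[cat]] <- c(evidence[[cat]], p$evidence[[cat]])
  }
  structure(list(flags = flags, evidence = evidence), class = "comorbidity_profile")
}

#' @export
print.comorbidity_profile <- function(x, ...) {
  on <- names(x$flags)[x$flags]
  cat("<comorbidity_profile>",
      if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}
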