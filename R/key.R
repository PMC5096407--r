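# Executable dichotomous key. Couplets hold leads; each lead carries a
# conjunction of atomic predicates over a small controlled trait
# vocabulary, the verbatim lead text for display, and either a next-couplet
# reference or one or more terminal taxa. Traversal uses three-valued
# logic: a lead is followed when its condition is definitely true; when no
# lead is definitely true, every lead not definitely false is followed and
# the couplet is reported as an ambiguity point.

#' Load the packaged identification key
#' @return a list of class `identification_key`.
#' @export
load_key <- function() {
  path <- system.file("extdata", "pseudobranchiomma_key.json",
                      package = "morphparsimony", mustWork = TRUE)
  key <- jsonlite::read_json(path)
  class(key) <- "identification_key"
  key
}

#' @export
print.identification_key <- function(x, ...) {
  cat(x$title, "\n")
  cat(sprintf("%d couplets, %d terminal species, %d traits\n",
              length(x$couplets), x$n_species, length(x$traits)))
  invisible(x)
}

# three-valued evaluation of one atomic predicate: TRUE / FALSE / NA
eval_atom <- function(atom, obs) {
  val <- obs[[atom$trait]]
  if (is.null(val) || is.na(val)) return(NA)
  target <- atom$value
  switch(atom$op,
         eq = isTRUE(val == target),
         le = isTRUE(val <= target),
         ge = isTRUE(val >= target),
         range = isTRUE(val >= target[[1L]]) && isTRUE(val <= target[[2L]]),
         mp_stop("key_structure_error", paste0("unknown op '", atom$op, "'")))
}

# conjunction with three-valued logic
eval_condition <- function(cond, obs) {
  vals <- vapply(cond, eval_atom, logical(1L), obs = obs)
  if (any(vals %in% FALSE)) return(FALSE)
  if (anyNA(vals)) return(NA)
  TRUE
}

key_terminals <- function(key) {
  sort(unique(unlist(lapply(key$couplets, function(cp)
    unlist(lapply(cp$leads, function(l) unlist(l$taxa)))))))
}

#' Identify a specimen from trait observations
#'
#' Traverses the key from couplet 1. Unknown traits cause both leads of an
#' undecidable couplet to be followed; the result then lists every
#' reachable terminal and flags the couplets where the path forked.
#' Observations contradicting every lead of a couplet raise a
#' `key_no_path_error` naming the couplet.
#'
#' @param observations named list of trait values (logical or count);
#'   omitted traits are unknown.
#' @param key an `identification_key` (default: the packaged key).
#' @return list of class `key_result`: `taxa` (candidate species),
#'   `ambiguous_at` (couplet ids where both leads were followed),
#'   `cautions` (texts of caution-flagged leads on the path), `paths`
#'   (visited couplet ids).
#' @export
identify_specimen <- function(observations = list(), key = load_key()) {
  unknown <- setdiff(names(observations), names(key$traits))
  if (length(unknown))
    mp_stop("key_structure_error",
            paste0("unknown trait(s): ", paste(unknown, collapse = ", ")))
  couplets <- stats::setNames(key$couplets,
                              vapply(key$couplets, `[[`, numeric(1L), "id"))
  taxa <- character(0)
  ambiguous <- integer(0)
  cautions <- character(0)
  visited <- integer(0)
  walk <- function(id) {
    visited <<- c(visited, id)
    cp <- couplets[[as.character(id)]]
    if (is.null(cp))
      mp_stop("key_structure_error", paste0("missing couplet ", id))
    verdicts <- lapply(cp$leads, function(l) eval_condition(l$condition,
                                                            observations))
    truth <- vapply(verdicts, isTRUE, logical(1L))
    nonfalse <- which(!vapply(verdicts, isFALSE, logical(1L)))
    if (!length(nonfalse))
      mp_stop("key_no_path_error",
              paste0("observations match no lead of couplet ", id),
              couplet = id)
    if (any(truth) && all(nonfalse %in% which(truth))) {
      # every viable lead is definitely true: printed order decides
      follow <- which(truth)[1L]
    } else {
      # undecidable leads remain: follow every lead not ruled out
      follow <- nonfalse
      if (length(follow) > 1L) ambiguous <<- c(ambiguous, id)
    }
    for (i in follow) {
      lead <- cp$leads[[i]]
      if (isTRUE(lead$caution)) cautions <<- c(cautions, lead$text)
      if (!is.null(lead$goto)) walk(lead$goto)
      else taxa <<- c(taxa, unlist(lead$taxa))
    }
  }
  walk(1L)
  structure(list(taxa = sort(unique(taxa)),
                 ambiguous_at = unique(ambiguous),
                 cautions = unique(cautions),
                 path = visited),
            class = "key_result")
}

#' @export
print.key_result <- function(x, ...) {
  if (length(x$taxa) == 1L) cat("identified as:", x$taxa, "\n")
  else cat("candidates:", paste(x$taxa, collapse = "; "), "\n")
  if (length(x$ambiguous_at))
    cat("ambiguous at couplet(s):", paste(x$ambiguous_at, collapse = ", "), "\n")
  if (length(x$cautions))
    cat("caution: key authors flag", length(x$cautions),
        "lead(s) on this path as weak\n")
  invisible(x)
}

#' Validate the structural integrity of a key
#'
#' Checks that every couplet reference resolves, that the lead graph is
#' acyclic, that every terminal species is reachable from couplet 1, and
#' that the terminal species count matches the declared number of valid
#' species.
#'
#' @param key an `identification_key`.
#' @return list of class `key_report` with `n_couplets`, `n_species`,
#'   `terminals`, `acyclic`, `all_reachable`.
#' @export
validate_key <- function(key = load_key()) {
  couplets <- stats::setNames(key$couplets,
                              vapply(key$couplets, `[[`, numeric(1L), "id"))
  ids <- as.integer(names(couplets))
  # resolve references
  for (cp in key$couplets) {
    for (l in cp$leads) {
      if (!is.null(l$goto) && !(l$goto %in% ids))
        mp_stop("key_structure_error",
                paste0("couplet ", cp$id, " points to missing couplet ",
                       l$goto))
      if (is.null(l$goto) && !length(unlist(l$taxa)))
        mp_stop("key_structure_error",
                paste0("couplet ", cp$id, " has a lead with no outcome"))
    }
  }
  # acyclicity and reachability via DFS with an active-path stack
  acyclic <- TRUE
  reached <- integer(0)
  terminals <- character(0)
  dfs <- function(id, active) {
    if (id %in% active) {
      acyclic <<- FALSE
      return(invisible())
    }
    reached <<- unique(c(reached, id))
    cp <- couplets[[as.character(id)]]
    for (l in cp$leads) {
      if (!is.null(l$goto)) dfs(l$goto, c(active, id))
      else terminals <<- unique(c(terminals, unlist(l$taxa)))
    }
  }
  dfs(1L, integer(0))
  if (!acyclic)
    mp_stop("key_structure_error", "key contains a couplet cycle")
  all_species <- key_terminals(key)
  all_reachable <- all(all_species %in% terminals) &&
    all(ids %in% reached)
  if (!all_reachable)
    mp_stop("key_structure_error",
            "some couplets or terminal species are unreachable from couplet 1")
  if (length(all_species) != key$n_species)
    mp_stop("key_structure_error",
            sprintf("key names %d species; %d declared",
                    length(all_species), key$n_species))
  structure(list(n_couplets = length(ids),
                 n_species = length(all_species),
                 terminals = all_species,
                 acyclic = acyclic,
                 all_reachable = all_reachable),
            class = "key_report")
}

#' @export
print.key_report <- function(x, ...) {
  cat(sprintf("key OK: %d couplets, %d species, acyclic, all reachable\n",
              x$n_couplets, x$n_species))
  invisible(x)
}
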