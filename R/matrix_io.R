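# Character-matrix container and NEXUS / TNT / CSV dialects.
#
# Cells are stored as canonical token strings:
#   "0".."9"      determinate state
#   "[013]"       polymorphic (sorted digit run)
#   "?"           missing / unknown
#   "-"           inapplicable (en dash accepted on input)
#   "V"           variable (state span unstated in the source matrix)

#' Construct a character matrix
#'
#' @param cells character matrix of cell tokens (taxa in rows, characters in
#'   columns); see Details for the token conventions.
#' @param taxa taxon names (defaults to rownames of `cells`).
#' @param characters optional data frame with columns `index`, `label` and
#'   `ordered`; a default frame of unordered, unlabelled characters is built
#'   when omitted.
#' @param outgroup optional taxon name used to root displayed trees.
#'
#' @details Determinate states are single digits, polymorphic cells are
#'   bracketed digit runs such as `"[01]"`, `"?"` is missing, `"-"` (or the
#'   en dash) inapplicable, and `"V"` marks a cell recorded as variable
#'   without an enumerated state span. All characters are treated as
#'   unordered (non-additive).
#'
#' @return An object of class `character_matrix`.
#' @export
character_matrix <- function(cells, taxa = rownames(cells), characters = NULL,
                             outgroup = NULL) {
  cells <- as.matrix(cells)
  if (is.null(taxa)) mp_stop("matrix_shape_error", "taxon names are required")
  taxa <- as.character(taxa)
  if (length(taxa) != nrow(cells))
    mp_stop("matrix_shape_error", "taxa length does not match cell rows")
  if (anyDuplicated(taxa))
    mp_stop("duplicate_taxon_error",
            paste0("duplicate taxon name: ",
                   taxa[duplicated(taxa)][1L]))
  if (length(cells)) {
    cells <- matrix(vapply(cells, canonical_token, character(1L)),
                    nrow = nrow(cells),
                    dimnames = list(taxa, colnames(cells)))
  } else {
    dimnames(cells) <- list(taxa, colnames(cells))
  }
  if (is.null(characters)) {
    characters <- data.frame(index = seq_len(ncol(cells)),
                             label = sprintf("char%d", seq_len(ncol(cells))),
                             ordered = rep(FALSE, ncol(cells)))
  }
  stopifnot(nrow(characters) == ncol(cells))
  if (!is.null(outgroup) && !is.na(outgroup) && !(outgroup %in% taxa))
    mp_stop("matrix_shape_error",
            paste0("outgroup '", outgroup, "' is not among the taxa"))
  structure(list(taxa = taxa,
                 cells = cells,
                 characters = characters,
                 outgroup = if (is.null(outgroup)) NA_character_ else outgroup),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters\n",
              length(x$taxa), ncol(x$cells)))
  if (!is.na(x$outgroup)) cat("outgroup:", x$outgroup, "\n")
  n_missing <- sum(x$cells == "?")
  n_inapp <- sum(x$cells == "-")
  cat(sprintf("cells: %d missing (?), %d inapplicable (-), %d variable (V)\n",
              n_missing, n_inapp, sum(x$cells == "V")))
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$cells)

# normalize one token; signals symbol_error for anything unrecognized
canonical_token <- function(tok, row = NA, col = NA) {
  tok <- gsub("–", "-", trimws(tok))  # en dash -> hyphen
  if (tok %in% c("?", "-")) return(tok)
  if (toupper(tok) == "V") return("V")
  if (grepl("^[0-9]$", tok)) return(tok)
  first <- substr(tok, 1L, 1L)
  last <- substr(tok, nchar(tok), nchar(tok))
  closer <- c("[" = "]", "{" = "}", "(" = ")")
  if (first %in% names(closer) && identical(unname(closer[first]), last) &&
      grepl("^[0-9 ]+$", substr(tok, 2L, nchar(tok) - 1L))) {
    digits <- sort(unique(strsplit(gsub("[^0-9]", "", tok), "")[[1L]]))
    if (length(digits) < 2L)
      mp_stop("symbol_error",
              paste0("polymorphic cell with fewer than two states: '", tok, "'"))
    return(paste0("[", paste(digits, collapse = ""), "]"))
  }
  mp_stop("symbol_error",
          paste0("unrecognized state symbol '", tok, "'",
                 if (!is.na(row)) paste0(" at taxon ", row, ", character ", col)
                 else ""))
}

# whitespace -> single underscore (newick-safe); used for NEXUS/TNT output
internal_name <- function(x) gsub("\\s+", "_", trimws(x))

#' Cell states of one matrix cell
#'
#' Decode a cell token into its kind and integer state set, mirroring the
#' matrix legend: `?` missing, `-` inapplicable, `V` variable, digits
#' determinate, bracketed runs polymorphic.
#'
#' @param m a [character_matrix].
#' @param taxon taxon name or row index.
#' @param character character index (1-based).
#' @return list with `kind` (one of `determinate`, `polymorphic`, `missing`,
#'   `inapplicable`, `variable`) and `states` (integer vector, empty for
#'   missing/inapplicable/variable cells).
#' @export
cell_state <- function(m, taxon, character) {
  if (is.character(taxon)) taxon <- match(taxon, m$taxa)
  tok <- m$cells[taxon, character]
  if (tok == "?") return(list(kind = "missing", states = integer()))
  if (tok == "-") return(list(kind = "inapplicable", states = integer()))
  if (tok == "V") return(list(kind = "variable", states = integer()))
  if (grepl("^\\[", tok)) {
    return(list(kind = "polymorphic",
                states = as.integer(strsplit(gsub("[^0-9]", "", tok), "")[[1L]])))
  }
  list(kind = "determinate", states = as.integer(tok))
}

# ---------------------------------------------------------------------------
# State bitmasks for the scoring engine.
# ---------------------------------------------------------------------------

# Observed (determinate or polymorphic) states per column.
observed_states <- function(cells_col) {
  toks <- cells_col[!(cells_col %in% c("?", "-", "V"))]
  sort(unique(as.integer(strsplit(paste(gsub("[^0-9]", "", toks), collapse = ""),
                                  "")[[1L]])))
}

#' State bitmask matrix for Fitch scoring
#'
#' Missing (`?`), inapplicable (`-`) and variable (`V`) cells all carry the
#' full observed-state set of their column, so they can never add steps.
#' Under this engine the two documented readings of `V` (full uncertainty
#' vs. polymorphism over all states observed in the character) produce the
#' same mask; the switch is retained for cell-kind reporting and output.
#'
#' @param m a [character_matrix].
#' @param variable_as how `V` cells are interpreted (`"missing"` or
#'   `"polymorphic"`); see Details.
#' @return integer matrix (taxa x characters) of state bitmasks.
#' @export
state_masks <- function(m, variable_as = c("missing", "polymorphic")) {
  variable_as <- match.arg(variable_as)
  n <- length(m$taxa)
  k <- ncol(m$cells)
  out <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    obs <- observed_states(m$cells[, j])
    full <- if (length(obs)) sum(bitwShiftL(1L, obs)) else 1L
    for (i in seq_len(n)) {
      tok <- m$cells[i, j]
      out[i, j] <-
        if (tok %in% c("?", "-", "V")) full
        else {
          digs <- as.integer(strsplit(gsub("[^0-9]", "", tok), "")[[1L]])
          sum(bitwShiftL(1L, digs))
        }
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Readers
# ---------------------------------------------------------------------------

# accepts a file path or a character vector of text lines
source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    return(readLines(source, warn = FALSE))
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

#' Read a character matrix
#'
#' @param source file path or character vector of text.
#' @param dialect one of `"csv"`, `"nexus"`, `"tnt"`.
#' @param outgroup optional outgroup taxon.
#' @return a [character_matrix].
#' @export
read_matrix <- function(source, dialect = c("csv", "nexus", "tnt"),
                        outgroup = NULL) {
  dialect <- match.arg(dialect)
  lines <- source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    mp_stop("matrix_shape_error", "empty input stream")
  switch(dialect,
         csv = read_matrix_csv(lines, outgroup),
         nexus = read_matrix_nexus(lines, outgroup),
         tnt = read_matrix_tnt(lines, outgroup))
}

read_matrix_csv <- function(lines, outgroup) {
  parts <- strsplit(lines, ",", fixed = TRUE)
  header <- trimws(parts[[1L]])
  rows <- parts[-1L]
  if (!length(rows)) mp_stop("matrix_shape_error", "no taxon rows")
  ncell <- length(header) - 1L
  taxa <- character(length(rows))
  cells <- matrix("", length(rows), ncell)
  for (i in seq_along(rows)) {
    r <- trimws(rows[[i]])
    if (length(r) != ncell + 1L)
      mp_stop("matrix_shape_error",
              paste0("row ", i, " has ", length(r) - 1L,
                     " cells; expected ", ncell))
    taxa[i] <- r[1L]
    for (j in seq_len(ncell)) cells[i, j] <- canonical_token(r[j + 1L], r[1L], j)
  }
  if (anyDuplicated(taxa))
    mp_stop("duplicate_taxon_error",
            paste0("duplicate taxon name: ", taxa[duplicated(taxa)][1L]))
  character_matrix(cells, taxa = taxa, outgroup = outgroup)
}

# split a concatenated state string ("00-1?[01]V...") into cell tokens
split_state_string <- function(s, taxon) {
  chars <- strsplit(s, "")[[1L]]
  toks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("[", "{", "(")) {
      close <- c("[" = "]", "{" = "}", "(" = ")")[[ch]]
      j <- i
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars))
        mp_stop("symbol_error",
                paste0("unterminated polymorphism group for taxon ", taxon))
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == " ") {
      i <- i + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  vapply(toks, canonical_token, character(1L), row = taxon)
}

parse_block_rows <- function(rows, outgroup) {
  taxa <- vapply(rows, `[[`, character(1L), 1L)
  if (anyDuplicated(taxa))
    mp_stop("duplicate_taxon_error",
            paste0("duplicate taxon name: ", taxa[duplicated(taxa)][1L]))
  cell_list <- lapply(rows, function(r) split_state_string(r[[2L]], r[[1L]]))
  ncell <- length(cell_list[[1L]])
  for (i in seq_along(cell_list))
    if (length(cell_list[[i]]) != ncell)
      mp_stop("matrix_shape_error",
              paste0("taxon ", taxa[i], " has ", length(cell_list[[i]]),
                     " cells; expected ", ncell))
  cells <- do.call(rbind, cell_list)
  character_matrix(cells, taxa = taxa, outgroup = outgroup)
}

read_matrix_nexus <- function(lines, outgroup) {
  txt <- lines
  start <- grep("^\\s*matrix\\s*$", tolower(txt))
  if (!length(start))
    mp_stop("matrix_shape_error", "no MATRIX block found in NEXUS input")
  body <- txt[(start[1L] + 1L):length(txt)]
  end <- grep("^\\s*;", body)
  if (length(end)) body <- body[seq_len(end[1L] - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) mp_stop("matrix_shape_error", "empty MATRIX block")
  rows <- lapply(body, function(l) {
    l <- trimws(l)
    m <- regmatches(l, regexec("^(\\S+)\\s+(.*)$", l))[[1L]]
    if (length(m) < 3L)
      mp_stop("matrix_shape_error", paste0("cannot parse NEXUS row: ", l))
    list(gsub("^'|'$", "", m[2L]), m[3L])
  })
  parse_block_rows(rows, outgroup)
}

read_matrix_tnt <- function(lines, outgroup) {
  txt <- lines
  xi <- grep("^\\s*xread", tolower(txt))
  if (!length(xi))
    mp_stop("matrix_shape_error", "no xread block found in TNT input")
  body <- txt[(xi[1L] + 1L):length(txt)]
  # skip optional quoted title and the "nchar ntax" line
  body <- body[!grepl("^\\s*'", body)]
  dimline <- grep("^\\s*\\d+\\s+\\d+\\s*$", body)
  if (length(dimline)) body <- body[-dimline[1L]]
  end <- grep("^\\s*;", body)
  if (length(end)) body <- body[seq_len(end[1L] - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) mp_stop("matrix_shape_error", "empty xread block")
  rows <- lapply(body, function(l) {
    l <- trimws(l)
    m <- regmatches(l, regexec("^(\\S+)\\s+(.*)$", l))[[1L]]
    if (length(m) < 3L)
      mp_stop("matrix_shape_error", paste0("cannot parse TNT row: ", l))
    list(m[2L], m[3L])
  })
  parse_block_rows(rows, outgroup)
}

# ---------------------------------------------------------------------------
# Writers
# ---------------------------------------------------------------------------

#' Write a character matrix to text
#'
#' @param m a [character_matrix].
#' @param dialect one of `"csv"`, `"nexus"`, `"tnt"`.
#' @return a character vector of text lines.
#' @export
write_matrix <- function(m, dialect = c("csv", "nexus", "tnt")) {
  dialect <- match.arg(dialect)
  if (!length(m$taxa))
    mp_stop("dialect_error", "cannot serialize a matrix with no taxa")
  nchar_ <- ncol(m$cells)
  if (dialect %in% c("nexus", "tnt")) {
    states <- unlist(lapply(seq_len(nchar_), function(j)
      observed_states(m$cells[, j])))
    if (length(states) && max(states) > 9L)
      mp_stop("dialect_error",
              "states above 9 cannot be written as single symbols")
  }
  switch(dialect,
         csv = {
           if (any(grepl(",", m$taxa, fixed = TRUE)))
             mp_stop("dialect_error", "taxon names containing ',' cannot be written as CSV")
           header <- paste(c("taxon", seq_len(nchar_)), collapse = ",")
           rows <- vapply(seq_along(m$taxa), function(i)
             paste(c(m$taxa[i], m$cells[i, ]), collapse = ","),
             character(1L))
           c(header, rows)
         },
         nexus = {
           symbols <- paste(sort(unique(unlist(lapply(seq_len(nchar_), function(j)
             observed_states(m$cells[, j]))))), collapse = "")
           name <- internal_name(m$taxa)
           pad <- max(nchar(name)) + 2L
           rows <- vapply(seq_along(m$taxa), function(i) {
             toks <- m$cells[i, ]
             toks <- ifelse(grepl("^\\[", toks),
                            paste0("{", gsub("[^0-9]", "", toks), "}"), toks)
             paste0(formatC(name[i], width = -pad), paste(toks, collapse = ""))
           }, character(1L))
           c("#NEXUS",
             "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(m$taxa), nchar_),
             sprintf("FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"%s\";",
                     symbols),
             "MATRIX",
             rows,
             ";",
             "END;")
         },
         tnt = {
           name <- internal_name(m$taxa)
           pad <- max(nchar(name)) + 2L
           rows <- vapply(seq_along(m$taxa), function(i)
             paste0(formatC(name[i], width = -pad),
                    paste(m$cells[i, ], collapse = "")),
             character(1L))
           c("xread",
             "'morphparsimony character matrix'",
             sprintf("%d %d", nchar_, length(m$taxa)),
             rows,
             ";")
         })
}

# ---------------------------------------------------------------------------
# Fixtures
# ---------------------------------------------------------------------------

#' Load a packaged character matrix
#'
#' `"table1"` is the full 26-taxon, 33-character sabellid matrix;
#' `"table5"` is the reduced 11-taxon matrix for the terminals with DNA
#' data. Both come with the outgroup preset to the *Pseudopotamilla*
#' terminal and the character labels attached.
#'
#' @param name `"table1"` or `"table5"`.
#' @return a [character_matrix].
#' @export
load_fixture <- function(name = c("table1", "table5")) {
  if (!is.character(name) || !name[1L] %in% c("table1", "table5"))
    mp_stop("unknown_fixture_error",
            paste0("unknown fixture '", name[1L], "'"))
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "morphparsimony", mustWork = TRUE)
  m <- read_matrix(path, dialect = "csv")
  m$outgroup <- m$taxa[grep("^Pseudopotamilla", m$taxa)][1L]
  defs_path <- system.file("extdata", "characters.csv",
                           package = "morphparsimony", mustWork = TRUE)
  defs <- utils::read.csv(defs_path, stringsAsFactors = FALSE)
  m$characters <- data.frame(index = defs$index, label = defs$label,
                             ordered = FALSE)
  m
}

# subset taxa (keeps character definitions); used by searches and resampling
subset_taxa <- function(m, taxa) {
  idx <- if (is.character(taxa)) match(taxa, m$taxa) else taxa
  if (anyNA(idx)) mp_stop("leaf_set_error", "unknown taxon in subset")
  og <- if (!is.na(m$outgroup) && m$outgroup %in% m$taxa[idx]) m$outgroup else NULL
  character_matrix(m$cells[idx, , drop = FALSE], taxa = m$taxa[idx],
                   characters = m$characters, outgroup = og)
}

# subset characters; used by the jackknife and the ratchet
subset_characters <- function(m, chars) {
  character_matrix(m$cells[, chars, drop = FALSE], taxa = m$taxa,
                   characters = m$characters[chars, , drop = FALSE],
                   outgroup = if (is.na(m$outgroup)) NULL else m$outgroup)
}
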