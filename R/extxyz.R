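# Extended-XYZ reader/writer.
#
# Dialect: the comment line carries space-separated key=value pairs with
# double-quoted values where needed, plus an ASE-style Properties= descriptor.
# Recognized keys: id, charge, multiplicity, energy, Properties.  Per-atom
# charge channels are the columns q_alpha / q_beta.  Numbers are written with
# 17 significant digits so write -> read round trips are lossless.

.split_comment_line <- function(line) {
  # split on spaces outside double quotes
  chars <- strsplit(line, "")[[1]]
  out <- character(0); buf <- character(0); inq <- FALSE
  for (ch in chars) {
    if (ch == '"') { inq <- !inq; next }
    if (ch == " " && !inq) {
      if (length(buf)) { out <- c(out, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  if (length(buf)) out <- c(out, paste(buf, collapse = ""))
  out
}

.parse_kv <- function(tokens) {
  kv <- list()
  for (tok in tokens) {
    eq <- regexpr("=", tok, fixed = TRUE)
    if (eq < 0) next
    key <- substr(tok, 1L, eq - 1L)
    kv[[key]] <- substr(tok, eq + 1L, nchar(tok))
  }
  kv
}

.parse_properties <- function(spec) {
  # e.g. "species:S:1:pos:R:3:q_alpha:R:1:q_beta:R:1"
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) %% 3L != 0L)
    stop("malformed Properties descriptor: ", spec, call. = FALSE)
  m <- matrix(parts, ncol = 3L, byrow = TRUE)
  data.frame(name = m[, 1], type = m[, 2],
             ncol = as.integer(m[, 3]), stringsAsFactors = FALSE)
}

#' Read an extended-XYZ file
#'
#' Parses a (multi-record) extended-XYZ file.  Charge/multiplicity and
#' per-atom `q_alpha`/`q_beta` columns are picked up from the key=value
#' comment-line dialect when present.
#'
#' @param path file path.
#' @return List of records; each record is a list with `conformer` and,
#'   when present in the file, `spin_state`, `energy` and an N x 2 `charges`
#'   matrix.  Records carrying all label fields can be converted with
#'   [labeled_sample()].
#' @seealso [write_extxyz()]
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  records <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("line %d: expected a positive atom count, got '%s'",
                   ln, lines[ln]), call. = FALSE)
    if (ln + 1L + nat > length(lines))
      stop(sprintf(paste0("line %d: record declares %d atoms but the file ",
                          "ends at line %d"),
                   ln, nat, length(lines)), call. = FALSE)
    kv <- .parse_kv(.split_comment_line(lines[ln + 1L]))
    props <- .parse_properties(
      if (is.null(kv$Properties)) "species:S:1:pos:R:3" else kv$Properties)
    if (props$name[1] != "species" || props$ncol[1] != 1L)
      stop(sprintf("line %d: Properties must start with species:S:1", ln + 1L),
           call. = FALSE)
    ncol_tot <- sum(props$ncol)

    atom_lines <- lines[(ln + 2L):(ln + 1L + nat)]
    fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
    elements <- character(nat)
    cols <- matrix(NA_real_, nat, ncol_tot - 1L)  # numeric columns after species
    for (a in seq_len(nat)) {
      f <- fields[[a]]
      lineno <- ln + 1L + a
      if (length(f) != ncol_tot)
        stop(sprintf("line %d: expected %d fields, got %d",
                     lineno, ncol_tot, length(f)), call. = FALSE)
      elements[a] <- f[1]
      vals <- suppressWarnings(as.numeric(f[-1]))
      if (anyNA(vals))
        stop(sprintf("line %d: non-numeric coordinate or column value",
                     lineno), call. = FALSE)
      cols[a, ] <- vals
    }
    if (!all(elements %in% supported_elements()))
      stop(sprintf("line %d: unknown element '%s'",
                   ln + 1L + which(!elements %in% supported_elements())[1],
                   setdiff(elements, supported_elements())[1]), call. = FALSE)

    # map numeric columns to named blocks
    offs <- cumsum(c(0L, props$ncol))[-nrow(props) - 1L]
    blocks <- list()
    for (p in seq_len(nrow(props))) {
      if (props$name[p] == "species") next
      idx <- (offs[p] - 1L) + seq_len(props$ncol[p])  # -1: species col dropped
      blocks[[props$name[p]]] <- cols[, idx, drop = FALSE]
    }
    if (is.null(blocks$pos))
      stop(sprintf("line %d: Properties descriptor lacks a pos field", ln + 1L),
           call. = FALSE)

    conf <- conformer(elements, blocks$pos,
                      id = if (is.null(kv$id)) "" else kv$id)
    rec <- list(conformer = conf)
    if (!is.null(kv$charge) && !is.null(kv$multiplicity)) {
      rec$spin_state <- spin_state(as.integer(kv$charge),
                                   as.integer(kv$multiplicity),
                                   n_electrons(conf, as.integer(kv$charge)))
    }
    if (!is.null(kv$energy)) rec$energy <- as.numeric(kv$energy)
    if (!is.null(blocks$q_alpha) && !is.null(blocks$q_beta))
      rec$charges <- cbind(blocks$q_alpha[, 1], blocks$q_beta[, 1])
    records[[length(records) + 1L]] <- rec
    ln <- ln + 2L + nat
    while (ln <= length(lines) && !nzchar(trimws(lines[ln]))) ln <- ln + 1L
  }
  records
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write records to an extended-XYZ file
#'
#' @param records a list of records as returned by [read_extxyz()], a list of
#'   [labeled_sample()] objects, or a single `conformer`/`labeled_sample`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(records, path) {
  if (inherits(records, c("conformer", "labeled_sample"))) records <- list(records)
  out <- character(0)
  for (rec in records) {
    if (inherits(rec, "conformer")) rec <- list(conformer = rec)
    if (inherits(rec, "labeled_sample"))
      rec <- list(conformer = rec$conformer, spin_state = rec$spin_state,
                  energy = rec$energy, charges = rec$charges)
    conf <- rec$conformer
    n <- length(conf$elements)
    has_q <- !is.null(rec$charges)
    props <- paste0("species:S:1:pos:R:3",
                    if (has_q) ":q_alpha:R:1:q_beta:R:1" else "")
    kv <- c(sprintf("Properties=%s", props))
    if (nzchar(conf$id)) kv <- c(kv, sprintf('id="%s"', conf$id))
    if (!is.null(rec$spin_state))
      kv <- c(kv, sprintf("charge=%d", rec$spin_state$charge),
              sprintf("multiplicity=%d", rec$spin_state$multiplicity))
    if (!is.null(rec$energy)) kv <- c(kv, sprintf("energy=%s", .fmt_num(rec$energy)))
    out <- c(out, as.character(n), paste(kv, collapse = " "))
    for (a in seq_len(n)) {
      line <- paste(c(conf$elements[a], .fmt_num(conf$coords[a, ]),
                      if (has_q) .fmt_num(rec$charges[a, ])), collapse = " ")
      out <- c(out, line)
    }
  }
  writeLines(out, path)
  invisible(path)
}
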