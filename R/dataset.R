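# Size-grouped dataset container.
#
# Records are grouped by atom count N so that training minibatches can be
# composed of molecules with the same number of atoms (padding-free batching).
# Each group stores parallel arrays; on disk a dataset is a directory with a
# manifest.json and one extended-XYZ file per group (plain text, lossless at
# 17 significant digits).

.empty_group <- function(n) {
  list(n_atoms = n, elements = matrix(character(0), 0, n),
       coords = array(numeric(0), c(0, n, 3)),
       charge = integer(0), multiplicity = integer(0),
       energy = numeric(0), charges = array(numeric(0), c(0, n, 2)),
       id = character(0))
}

#' Build a size-grouped dataset from labelled samples
#'
#' @param samples list of [labeled_sample()] objects (may be empty).
#' @return Object of class `"mol_dataset"`: a list of groups keyed by atom
#'   count, each group holding parallel arrays of element codes, coordinates,
#'   spin states, energies and per-atom channel charges.
#' @export
mol_dataset <- function(samples = list()) {
  groups <- list()
  sizes <- vapply(samples, function(s) length(s$conformer$elements), 1L)
  for (n in sort(unique(sizes))) {
    idx <- which(sizes == n)
    g <- .empty_group(n)
    b <- length(idx)
    g$elements <- matrix("", b, n)
    g$coords <- array(0, c(b, n, 3))
    g$charges <- array(0, c(b, n, 2))
    g$charge <- integer(b); g$multiplicity <- integer(b)
    g$energy <- numeric(b); g$id <- character(b)
    for (k in seq_len(b)) {
      s <- samples[[idx[k]]]
      g$elements[k, ] <- s$conformer$elements
      g$coords[k, , ] <- s$conformer$coords
      g$charges[k, , ] <- s$charges
      g$charge[k] <- s$spin_state$charge
      g$multiplicity[k] <- s$spin_state$multiplicity
      g$energy[k] <- s$energy
      g$id[k] <- s$conformer$id
    }
    groups[[as.character(n)]] <- g
  }
  structure(list(groups = groups), class = "mol_dataset")
}

.validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "mol_dataset"))
  for (key in names(ds$groups)) {
    g <- ds$groups[[key]]
    if (g$n_atoms != as.integer(key) || ncol(g$elements) != g$n_atoms)
      stop("group '", key, "' holds records with a different atom count",
           call. = FALSE)
  }
  invisible(ds)
}

#' Number of records in a dataset
#' @param ds a [mol_dataset()].
#' @export
n_records <- function(ds) {
  sum(vapply(ds$groups, function(g) length(g$energy), 1L))
}

#' @export
print.mol_dataset <- function(x, ...) {
  cat(sprintf("<mol_dataset> %d records in %d size groups\n",
              n_records(x), length(x$groups)))
  for (key in names(x$groups))
    cat(sprintf("  N = %s: %d records\n", key, length(x$groups[[key]]$energy)))
  invisible(x)
}

#' Flatten a dataset back to a list of labelled samples
#'
#' Iteration order within each size group is stable.
#'
#' @param ds a [mol_dataset()].
#' @return List of [labeled_sample()] objects.
#' @export
dataset_samples <- function(ds) {
  out <- list()
  for (key in names(ds$groups)) {
    g <- ds$groups[[key]]
    for (k in seq_along(g$energy)) {
      conf <- conformer(g$elements[k, ], matrix(g$coords[k, , ], ncol = 3),
                        id = g$id[k])
      st <- spin_state(g$charge[k], g$multiplicity[k],
                       n_electrons(conf, g$charge[k]))
      out[[length(out) + 1L]] <- labeled_sample(conf, st, g$energy[k],
                                                matrix(g$charges[k, , ],
                                                       ncol = 2))
    }
  }
  out
}

#' Write / read a dataset directory
#'
#' A dataset is stored as a directory containing `manifest.json` plus one
#' extended-XYZ file per size group.  The round trip is lossless (numbers are
#' written with 17 significant digits).
#'
#' @param ds a [mol_dataset()].
#' @param path directory path (created if missing).
#' @return `path` (write) or a `mol_dataset` (read).
#' @export
write_dataset <- function(ds, path) {
  .validate_dataset(ds)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "neqnet-dataset", version = 1L,
                   groups = lapply(ds$groups, function(g)
                     list(n_atoms = g$n_atoms, n_records = length(g$energy),
                          file = sprintf("group_%03d.xyz", g$n_atoms))))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (key in names(ds$groups)) {
    g <- ds$groups[[key]]
    recs <- lapply(seq_along(g$energy), function(k) {
      conf <- conformer(g$elements[k, ], matrix(g$coords[k, , ], ncol = 3),
                        id = g$id[k])
      list(conformer = conf,
           spin_state = spin_state(g$charge[k], g$multiplicity[k],
                                   n_electrons(conf, g$charge[k])),
           energy = g$energy[k], charges = matrix(g$charges[k, , ], ncol = 2))
    })
    write_extxyz(recs, file.path(path, sprintf("group_%03d.xyz", g$n_atoms)))
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a dataset directory (no manifest.json): ",
                             path, call. = FALSE)
  manifest <- jsonlite::read_json(mf)
  samples <- list()
  for (grp in manifest$groups) {
    recs <- read_extxyz(file.path(path, grp$file))
    if (length(recs) != grp$n_records)
      stop("group file ", grp$file, " holds ", length(recs),
           " records, manifest says ", grp$n_records, call. = FALSE)
    for (rec in recs) {
      if (length(rec$conformer$elements) != grp$n_atoms)
        stop("record with ", length(rec$conformer$elements),
             " atoms in group N = ", grp$n_atoms, call. = FALSE)
      samples[[length(samples) + 1L]] <-
        labeled_sample(rec$conformer, rec$spin_state, rec$energy, rec$charges)
    }
  }
  mol_dataset(samples)
}
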