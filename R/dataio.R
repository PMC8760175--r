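# Labeled SMILES table I/O.
#
# A dataset is a tibble with columns `id`, `smiles` (canonical), `label`
# (factor AIE/ACQ, NA allowed for unlabeled prediction sets), carrying a
# `rejected` attribute with the per-row rejection report. Invalid SMILES
# are never silently dropped.

new_dataset <- function(records, rejected = NULL) {
  rejected <- rejected %||%
    tibble::tibble(id = character(), smiles = character(),
                   reason = character())
  structure(records, rejected = rejected,
            class = c("aie_dataset", class(tibble::tibble())))
}

#' Read a labeled molecule table
#'
#' Reads a CSV (or whitespace-separated `.smi`) file of SMILES with
#' optional binary AIE/ACQ labels, validates and canonicalizes every
#' structure, and collects invalid rows into a rejection report available
#' via [rejected_records()].
#'
#' @param path Input file. `.smi` files are read as
#'   `SMILES<whitespace>id`; anything else as CSV with a header.
#' @param smiles_column,label_column,id_column Column names in the CSV.
#'   `label_column` may be `NULL` for unlabeled sets; a missing
#'   `id_column` autogenerates `m1, m2, ...` row ids.
#' @param label_aliases Mapping of accepted label spellings to the two
#'   classes; matching is case-insensitive. Defaults accept `AIE`/`ACQ`
#'   and the `1`/`0` aliases.
#' @return An `aie_dataset` tibble (`id`, `smiles`, `label`) of the valid
#'   rows, with the rejection report as an attribute.
#' @export
read_dataset <- function(path, smiles_column = "smiles",
                         label_column = "label", id_column = "id",
                         label_aliases = c(AIE = "AIE", ACQ = "ACQ",
                                           `1` = "AIE", `0` = "ACQ")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    raw <- readr::read_table(path, col_names = c("smiles", "id"),
                             col_types = readr::cols(
                               .default = readr::col_character()))
    if (all(is.na(raw$id))) raw$id <- paste0("m", seq_len(nrow(raw)))
    raw$label <- NA_character_
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             .default = readr::col_character()))
    if (!smiles_column %in% names(tab)) {
      abort(paste0("missing SMILES column '", smiles_column, "' in ",
                   path))
    }
    if (!is.null(label_column) && !label_column %in% names(tab)) {
      abort(paste0("missing label column '", label_column, "' in ", path))
    }
    raw <- tibble::tibble(
      id = if (!is.null(id_column) && id_column %in% names(tab)) {
        as.character(tab[[id_column]])
      } else {
        paste0("m", seq_len(nrow(tab)))
      },
      smiles = as.character(tab[[smiles_column]]),
      label = if (is.null(label_column)) NA_character_
              else as.character(tab[[label_column]])
    )
  }
  build_dataset(raw, label_aliases)
}

#' Assemble a dataset from an in-memory table
#'
#' @param records Data frame with columns `id`, `smiles` and optionally
#'   `label`.
#' @inheritParams read_dataset
#' @return An `aie_dataset`; see [read_dataset()].
#' @export
as_dataset <- function(records, label_aliases = c(AIE = "AIE", ACQ = "ACQ",
                                                  `1` = "AIE",
                                                  `0` = "ACQ")) {
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in%
                                          names(records)))
  if (!"label" %in% names(records)) records$label <- NA_character_
  build_dataset(tibble::as_tibble(records[, c("id", "smiles", "label")]),
                label_aliases)
}

build_dataset <- function(raw, label_aliases) {
  dup <- unique(raw$id[duplicated(raw$id)])
  if (length(dup)) {
    abort(paste0("duplicate id(s): ", paste(dup, collapse = ", ")))
  }

  lab <- rep(NA_character_, nrow(raw))
  has_lab <- !is.na(raw$label) & nzchar(trimws(raw$label))
  if (any(has_lab)) {
    key <- toupper(trimws(raw$label[has_lab]))
    map <- setNames(as.character(label_aliases),
                    toupper(names(label_aliases)))
    hit <- map[key]
    if (anyNA(hit)) {
      bad <- unique(key[is.na(hit)])
      abort(paste0("unrecognized label value(s): ",
                   paste(bad, collapse = ", ")))
    }
    lab[has_lab] <- hit
  }

  mols <- parse_molecules(raw$smiles, raw$id)
  ok <- !vapply(mols, is.null, logical(1))
  rejected <- tibble::tibble(
    id = raw$id[!ok], smiles = raw$smiles[!ok],
    reason = rep("SMILES parse failure", sum(!ok))
  )
  if (!any(ok)) abort("no valid molecules in input.")

  canon <- canonicalize_smiles(raw$smiles[ok])
  if (anyNA(canon)) {
    extra <- which(is.na(canon))
    rejected <- dplyr::bind_rows(rejected, tibble::tibble(
      id = raw$id[ok][extra], smiles = raw$smiles[ok][extra],
      reason = "canonicalization failure"))
    keep <- setdiff(seq_along(canon), extra)
  } else {
    keep <- seq_along(canon)
  }
  if (!length(keep)) abort("no valid molecules in input.")

  records <- tibble::tibble(
    id = raw$id[ok][keep],
    smiles = canon[keep],
    label = factor(lab[ok][keep], levels = c("ACQ", "AIE"))
  )
  new_dataset(records, rejected)
}

#' Rejection report of a dataset
#'
#' @param data An `aie_dataset`.
#' @return Tibble with columns `id`, `smiles`, `reason`, one row per
#'   rejected input record.
#' @export
rejected_records <- function(data) {
  attr(data, "rejected") %||%
    tibble::tibble(id = character(), smiles = character(),
                   reason = character())
}

#' Class counts of a dataset
#'
#' @param data An `aie_dataset` (or any tibble with a `label` column).
#' @return Named integer vector with counts for ACQ and AIE (labeled
#'   records only).
#' @export
class_counts <- function(data) {
  tab <- table(factor(data$label, levels = c("ACQ", "AIE")))
  setNames(as.integer(tab), names(tab))
}

#' @export
print.aie_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat("<aie_dataset> ", nrow(x), " molecules (AIE ", cc[["AIE"]],
      " / ACQ ", cc[["ACQ"]], "; unlabeled ",
      sum(is.na(x$label)), ")\n", sep = "")
  nrej <- nrow(rejected_records(x))
  if (nrej) cat("  +", nrej, "rejected rows (see rejected_records())\n")
  NextMethod()
}

#' Write a dataset / read it back
#'
#' @param data An `aie_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  out <- tibble::tibble(id = data$id, smiles = data$smiles,
                        label = as.character(data$label))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write ensemble predictions
#'
#' Serialises per-record vote tallies and final calls to CSV with columns
#' `id`, `smiles`, `votes_AIE`, `votes_ACQ`, `predicted_label`,
#' `vote_fraction` (and `tie` where an even panel split occurred). The
#' file round-trips losslessly through [read_predictions()].
#'
#' @param predictions Tibble as returned by [ensemble_predict()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("id", "smiles", "votes_AIE", "votes_ACQ", "predicted_label",
            "vote_fraction")
  if (!is.data.frame(predictions) || !all(need %in% names(predictions))) {
    abort(paste0("`predictions` must contain columns: ",
                 paste(need, collapse = ", ")))
  }
  if (nrow(predictions) == 0L) abort("empty prediction set.")
  if (any(predictions$votes_AIE + predictions$votes_ACQ <= 0)) {
    abort("every record needs at least one vote.")
  }
  readr::write_csv(predictions[, union(need, names(predictions))], path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    smiles = readr::col_character(),
                    votes_AIE = readr::col_integer(),
                    votes_ACQ = readr::col_integer(),
                    predicted_label = readr::col_character(),
                    vote_fraction = readr::col_double(),
                    .default = readr::col_guess()))
}
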