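# Domain container and on-disk formats.
#
# The unit of storage is the reaction *variation*: one experimental run of a
# reaction with a specific chemical context, a yield and a date. Variations
# sharing a record_id describe the same chemical transformation (identical
# reactants and product). A ReactionDataset holds one row per variation,
# mirroring the on-disk CSV schema exactly; readers group rows into records
# by record_id and writers emit one row per variation.

.ROLES <- c("catalyst", "pre-catalyst", "ligand", "base", "solvent",
            "reagent", "unassigned")

.REQUIRED_COLS <- c("record_id", "reactant_smiles", "product_smiles",
                    "species_smiles", "species_roles", "yield_percent",
                    "date")

#' ReactionDataset: reaction records and their experimental variations
#'
#' An S4 container for Buchwald-Hartwig reaction data. The
#' \code{variations} slot is a data.frame with one row per experimental run
#' and columns \code{record_id}, \code{reactant_smiles} (dot-separated,
#' at least two reactants), \code{product_smiles} (a single molecule),
#' \code{species_smiles} (dot-separated context chemicals),
#' \code{species_roles} (semicolon-separated, aligned with
#' \code{species_smiles}), \code{yield_percent} in [0, 100] and \code{date}
#' (ISO-8601, year resolution required).
#'
#' @slot variations data.frame, one row per variation.
#' @slot provenance list of free-form metadata (source, generator seed, ...).
#' @export
setClass("ReactionDataset",
         representation(variations = "data.frame", provenance = "list"))

setValidity("ReactionDataset", function(object) {
  v <- object@variations
  msgs <- character(0)
  missing <- setdiff(.REQUIRED_COLS, names(v))
  if (length(missing))
    return(paste("missing variation columns:", paste(missing, collapse = ", ")))
  if (nrow(v) == 0)
    return(TRUE)  # empty dataset is permitted (e.g. before population)
  if (!is.numeric(v$yield_percent) ||
      any(is.na(v$yield_percent) | v$yield_percent < 0 | v$yield_percent > 100))
    msgs <- c(msgs, "yield_percent must be numeric in [0, 100]")
  yr <- suppressWarnings(as.integer(substr(v$date, 1, 4)))
  if (any(is.na(yr) | yr < 1990 | yr > 2100))
    msgs <- c(msgs, "date years must lie in [1990, 2100]")
  if (any(!nzchar(v$species_smiles)))
    msgs <- c(msgs, "every variation needs at least one context species")
  nreact <- lengths(strsplit(v$reactant_smiles, ".", fixed = TRUE))
  if (any(nreact < 2))
    msgs <- c(msgs, "a coupling needs >= 2 reactants per record")
  if (any(grepl(".", v$product_smiles, fixed = TRUE)))
    msgs <- c(msgs, "product_smiles must be a single molecule")
  roles <- unlist(strsplit(v$species_roles, ";", fixed = TRUE))
  if (!all(roles %in% .ROLES))
    msgs <- c(msgs, paste("unknown species role(s):",
                          paste(unique(setdiff(roles, .ROLES)), collapse = ", ")))
  nsp <- lengths(strsplit(v$species_smiles, ".", fixed = TRUE))
  nrl <- lengths(strsplit(v$species_roles, ";", fixed = TRUE))
  if (any(nsp != nrl))
    msgs <- c(msgs, "species_smiles and species_roles must align 1:1")
  # records must be internally consistent
  for (col in c("reactant_smiles", "product_smiles")) {
    if (any(tapply(v[[col]], v$record_id, function(x) length(unique(x))) > 1L)) {
      msgs <- c(msgs, paste0("record_id groups must share one ", col))
      break
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a ReactionDataset
#'
#' @param variations data.frame conforming to the variation schema (see
#'   \linkS4class{ReactionDataset}).
#' @param provenance list of metadata.
#' @return a validated \code{ReactionDataset}.
#' @export
ReactionDataset <- function(variations, provenance = list()) {
  variations <- as.data.frame(variations, stringsAsFactors = FALSE)
  rownames(variations) <- NULL
  methods::new("ReactionDataset", variations = variations,
               provenance = provenance)
}

#' @describeIn ReactionDataset-accessors variation table (one row per run)
#' @export
variations <- function(x) x@variations

#' Accessors for ReactionDataset
#'
#' @param x a \code{ReactionDataset}.
#' @name ReactionDataset-accessors
#' @return \code{variations}: the variation data.frame; \code{provenance}:
#'   the metadata list; \code{recordIds}: unique record identifiers;
#'   \code{nRecords}/\code{nVariations}: counts; \code{variationYears}:
#'   integer year per variation row.
NULL

#' @describeIn ReactionDataset-accessors provenance metadata
#' @export
provenance <- function(x) x@provenance

#' @describeIn ReactionDataset-accessors unique record ids
#' @export
recordIds <- function(x) unique(x@variations$record_id)

#' @describeIn ReactionDataset-accessors number of unique records
#' @export
nRecords <- function(x) length(recordIds(x))

#' @describeIn ReactionDataset-accessors number of variations (rows)
#' @export
nVariations <- function(x) nrow(x@variations)

#' @describeIn ReactionDataset-accessors calendar year of each variation
#' @export
variationYears <- function(x) as.integer(substr(x@variations$date, 1, 4))

setMethod("show", "ReactionDataset", function(object) {
  cat("ReactionDataset with", nRecords(object), "records and",
      nVariations(object), "variations\n")
  yrs <- variationYears(object)
  if (length(yrs))
    cat("  years:", min(yrs), "-", max(yrs), "\n")
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

.splitDot <- function(x) strsplit(x, ".", fixed = TRUE)
.splitSemi <- function(x) strsplit(x, ";", fixed = TRUE)

# Canonicalize every SMILES column of a variation table in one batch; rows
# containing unparseable SMILES are reported by row number.
.canonicalizeTable <- function(v, stripStereo = FALSE,
                               onInvalid = c("error", "drop")) {
  onInvalid <- match.arg(onInvalid)
  react <- .splitDot(v$reactant_smiles)
  spec <- .splitDot(v$species_smiles)
  all_smi <- c(unlist(react), v$product_smiles, unlist(spec))
  can <- canonicalizeSmiles(unique(all_smi), stripStereo = stripStereo,
                            mustWork = FALSE)
  names(can) <- unique(all_smi)
  lookup <- function(xs) unname(can[xs])
  bad_row <- vapply(seq_len(nrow(v)), function(i) {
    anyNA(lookup(c(react[[i]], v$product_smiles[i], spec[[i]])))
  }, logical(1))
  if (any(bad_row)) {
    if (onInvalid == "error")
      stop("unparseable SMILES in row(s): ",
           paste(which(bad_row), collapse = ", "), call. = FALSE)
    v <- v[!bad_row, , drop = FALSE]
    react <- react[!bad_row]
    spec <- spec[!bad_row]
  }
  v$reactant_smiles <- vapply(react, function(r)
    paste(sort(lookup(r)), collapse = "."), "")
  v$product_smiles <- lookup(v$product_smiles)
  v$species_smiles <- vapply(spec, function(s)
    paste(lookup(s), collapse = "."), "")
  attr(v, "dropped_rows") <- which(bad_row)
  v
}

#' Read a reaction dataset from CSV or JSON
#'
#' CSV holds one variation per row under the schema documented in
#' \linkS4class{ReactionDataset}; JSON holds a list of record objects with
#' nested variations (and supports species whose SMILES contain a dot,
#' which the flat CSV column cannot represent). A reaction-SMILES column
#' \code{rxn_smiles} ("reactants>agents>product") is accepted in CSV as an
#' alternative to the explicit columns; agents become context species with
#' role \code{unassigned}. All SMILES are canonicalized on read.
#'
#' @param path file path.
#' @param format "csv" or "json"; guessed from the file extension when
#'   omitted.
#' @param stripStereo drop stereochemistry during canonicalization.
#' @param onInvalid "error" (default) aborts naming the offending rows;
#'   "drop" removes them and records the row numbers in the provenance.
#' @return a \code{ReactionDataset}.
#' @export
readDataset <- function(path, format = c("auto", "csv", "json"),
                        stripStereo = FALSE, onInvalid = c("error", "drop")) {
  format <- match.arg(format)
  onInvalid <- match.arg(onInvalid)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    v <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
    if (nrow(v) == 0) stop("empty dataset file: ", path, call. = FALSE)
    if (!"reactant_smiles" %in% names(v) && "rxn_smiles" %in% names(v)) {
      parts <- strsplit(v$rxn_smiles, ">", fixed = TRUE)
      if (any(lengths(parts) != 3L))
        stop("rxn_smiles must have the form reactants>agents>product",
             call. = FALSE)
      v$reactant_smiles <- vapply(parts, `[[`, "", 1L)
      v$product_smiles <- vapply(parts, `[[`, "", 3L)
      agents <- vapply(parts, `[[`, "", 2L)
      v$species_smiles <- agents
      v$species_roles <- vapply(.splitDot(agents), function(a)
        paste(rep("unassigned", length(a)), collapse = ";"), "")
      v$rxn_smiles <- NULL
    }
    missing <- setdiff(.REQUIRED_COLS, names(v))
    if (length(missing))
      stop("dataset CSV is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    yield <- suppressWarnings(as.numeric(v$yield_percent))
    if (anyNA(yield))
      stop("non-numeric yield_percent in row(s): ",
           paste(which(is.na(yield)), collapse = ", "), call. = FALSE)
    v$yield_percent <- yield
  } else {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!length(recs)) stop("empty dataset file: ", path, call. = FALSE)
    rows <- lapply(recs, function(r) {
      do.call(rbind, lapply(r$variations, function(vv) {
        sp <- vv$species
        data.frame(
          record_id = r$record_id,
          reactant_smiles = paste(unlist(r$reactant_smiles), collapse = "."),
          product_smiles = r$product_smiles,
          species_smiles = paste(vapply(sp, `[[`, "", "smiles"),
                                 collapse = "."),
          species_roles = paste(vapply(sp, function(s)
            if (is.null(s$role)) "unassigned" else s$role, ""),
            collapse = ";"),
          yield_percent = as.numeric(vv$yield_percent),
          date = vv$date,
          stringsAsFactors = FALSE)
      }))
    })
    v <- do.call(rbind, rows)
  }
  v <- v[, .REQUIRED_COLS]
  v <- .canonicalizeTable(v, stripStereo = stripStereo, onInvalid = onInvalid)
  prov <- list(source = path, format = format)
  if (length(attr(v, "dropped_rows")))
    prov$dropped_rows <- attr(v, "dropped_rows")
  ReactionDataset(v, provenance = prov)
}

#' Write a reaction dataset to CSV or JSON
#'
#' Inverse of \code{\link{readDataset}}: \code{readDataset(writeDataset(ds))}
#' reproduces \code{ds} up to canonical SMILES and row order. The CSV format
#' cannot represent multi-fragment species SMILES (the species column is
#' dot-separated); such datasets must be written as JSON.
#'
#' @param ds a \code{ReactionDataset}.
#' @param path output file path.
#' @param format "csv" or "json" (guessed from the extension when omitted).
#' @return \code{path}, invisibly.
#' @export
writeDataset <- function(ds, path, format = c("auto", "csv", "json")) {
  stopifnot(methods::is(ds, "ReactionDataset"))
  methods::validObject(ds)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  v <- variations(ds)
  if (format == "csv") {
    n_sp <- lengths(.splitDot(v$species_smiles))
    n_rl <- lengths(.splitSemi(v$species_roles))
    if (any(n_sp != n_rl))
      stop("dataset contains multi-fragment species SMILES, which the ",
           "dot-separated CSV species column cannot represent; use the ",
           "JSON format instead", call. = FALSE)
    utils::write.csv(v, path, row.names = FALSE)
  } else {
    recs <- lapply(split(v, factor(v$record_id, levels = unique(v$record_id))),
                   function(g) {
      list(record_id = g$record_id[1],
           reactant_smiles = as.list(.splitDot(g$reactant_smiles[1])[[1]]),
           product_smiles = g$product_smiles[1],
           variations = lapply(seq_len(nrow(g)), function(i) {
             smi <- .splitDot(g$species_smiles[i])[[1]]
             rol <- .splitSemi(g$species_roles[i])[[1]]
             # roles align with fragments only for single-fragment species;
             # JSON keeps species as explicit objects so realign defensively
             if (length(smi) != length(rol)) {
               smi <- g$species_smiles[i]
               rol <- rol[1]
             }
             list(species = Map(function(s, r) list(smiles = s, role = r),
                                smi, rol, USE.NAMES = FALSE),
                  yield_percent = g$yield_percent[i],
                  date = g$date[i])
           }))
    })
    jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
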