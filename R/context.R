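# Chemical-context construction: role assignment, canonical context keys,
# the label space, and the single-label / multi-label training tables.

.CATEGORIES <- c("catalyst", "pre-catalyst", "ligand", "base", "solvent",
                 "reagent")

#' Load curated role lists
#'
#' Reads the plain-text curated lists (one SMILES per line) used for role
#' assignment: \code{catalysts.smi}, \code{precatalysts.smi},
#' \code{ligands.smi}, \code{bases.smi}, \code{solvents.smi}. The shipped
#' defaults cover common Buchwald-Hartwig species (Pd (pre-)catalysts,
#' phosphine ligands, alkoxide/carbonate/phosphate bases, ethereal and amide
#' solvents). All entries are canonicalized on load.
#'
#' @param dir directory containing the .smi files; defaults to the lists
#'   shipped with the package.
#' @return named list of character vectors of canonical SMILES with elements
#'   \code{catalysts}, \code{precatalysts}, \code{ligands}, \code{bases},
#'   \code{solvents}.
#' @export
curatedLists <- function(dir = system.file("extdata", "curated",
                                           package = "bhcontext")) {
  files <- c(catalysts = "catalysts.smi", precatalysts = "precatalysts.smi",
             ligands = "ligands.smi", bases = "bases.smi",
             solvents = "solvents.smi")
  lapply(files, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("curated list not found: ", p, call. = FALSE)
    smi <- readLines(p, warn = FALSE)
    smi <- smi[nzchar(trimws(smi))]
    unique(canonicalizeSmiles(trimws(smi)))
  })
}

#' Assign roles to context chemicals
#'
#' Fills in the role of every species whose role is \code{unassigned};
#' pre-assigned roles are kept untouched. Precedence for unassigned species:
#' curated pre-catalyst list, curated catalyst list, Pd/Pt-containing flag
#' (catalyst), curated solvent list, curated base list, curated ligand list,
#' and finally reagent for anything that matches nothing.
#'
#' @param species data.frame with columns \code{smiles} (canonical SMILES)
#'   and \code{role}; one row per context chemical.
#' @param curated curated role lists as returned by \code{\link{curatedLists}}.
#' @return the species data.frame with every role assigned.
#' @export
assignRoles <- function(species, curated = curatedLists()) {
  stopifnot(is.data.frame(species), all(c("smiles", "role") %in% names(species)))
  if (nrow(species) == 0)
    stop("a context must contain at least one species", call. = FALSE)
  todo <- species$role == "unassigned"
  if (!any(todo)) return(species)
  smi <- species$smiles[todo]
  role <- rep("reagent", length(smi))
  role[smi %in% curated$ligands] <- "ligand"
  role[smi %in% curated$bases] <- "base"
  role[smi %in% curated$solvents] <- "solvent"
  role[containsPdPt(smi)] <- "catalyst"
  role[smi %in% curated$catalysts] <- "catalyst"
  role[smi %in% curated$precatalysts] <- "pre-catalyst"
  species$role[todo] <- role
  species
}

#' Build the canonical context key for a set of context species
#'
#' A chemical context is the multiset of context species grouped by
#' category. Its key is a pure function of that content: canonical SMILES
#' are sorted lexicographically within each category, joined with ".", and
#' the six categories (catalyst, pre-catalyst, ligand, base, solvent,
#' reagent, in that fixed order) are joined with "|". Permuting the input
#' species never changes the key.
#'
#' @param species data.frame with columns \code{smiles} and \code{role};
#'   all roles must be assigned.
#' @return a single context key string.
#' @export
buildContextKey <- function(species) {
  stopifnot(is.data.frame(species))
  if (nrow(species) == 0)
    stop("a context must contain at least one species", call. = FALSE)
  if (any(species$role == "unassigned"))
    stop("all species roles must be assigned before building a context",
         call. = FALSE)
  paste(vapply(.CATEGORIES, function(cat) {
    paste(sort(species$smiles[species$role == cat]), collapse = ".")
  }, ""), collapse = "|")
}

#' Parse a context key back into its species
#'
#' @param key context key string produced by \code{\link{buildContextKey}}.
#' @return named list mapping each category to a character vector of
#'   canonical SMILES (possibly empty).
#' @export
contextSpecies <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  length(parts) <- length(.CATEGORIES)  # trailing empty fields
  parts[is.na(parts)] <- ""
  stats::setNames(lapply(parts, function(p)
    if (nzchar(p)) strsplit(p, ".", fixed = TRUE)[[1]] else character(0)),
    .CATEGORIES)
}

#' LabelSpace: the ordered set of predictable chemical contexts
#'
#' Contexts are ordered by descending usage count in the source data (ties
#' broken lexicographically by key), so label index 1 is the most popular
#' context.
#'
#' @slot contexts character vector of context keys; position = label index.
#' @slot counts integer usage counts aligned with \code{contexts}.
#' @export
setClass("LabelSpace",
         representation(contexts = "character", counts = "integer"))

setValidity("LabelSpace", function(object) {
  if (length(object@contexts) != length(object@counts))
    return("contexts and counts must align")
  if (anyDuplicated(object@contexts))
    return("context keys must be unique")
  n <- length(object@counts)
  if (n > 1) {
    o <- order(-object@counts, object@contexts)
    if (!identical(o, seq_len(n)))
      return("contexts must be sorted by descending count, ties by key")
  }
  TRUE
})

#' @describeIn LabelSpace-accessors ordered context keys
#' @export
labelKeys <- function(ls) ls@contexts

#' Accessors for LabelSpace
#' @param ls a \code{LabelSpace}.
#' @name LabelSpace-accessors
#' @return \code{labelKeys}: context keys in label order; \code{labelCounts}:
#'   usage counts; \code{nLabels}: number of contexts.
NULL

#' @describeIn LabelSpace-accessors usage counts per context
#' @export
labelCounts <- function(ls) ls@counts

#' @describeIn LabelSpace-accessors number of contexts
#' @export
nLabels <- function(ls) length(ls@contexts)

setMethod("show", "LabelSpace", function(object) {
  cat("LabelSpace with", nLabels(object), "contexts;",
      "counts", max(object@counts), "(top) to", min(object@counts),
      "(rarest)\n")
})

#' Serialize / deserialize a LabelSpace as JSON
#'
#' @param ls a \code{LabelSpace}.
#' @param path file path.
#' @return \code{readLabelSpace}: a \code{LabelSpace}.
#' @export
writeLabelSpace <- function(ls, path) {
  jsonlite::write_json(list(contexts = ls@contexts, counts = ls@counts),
                       path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeLabelSpace
#' @export
readLabelSpace <- function(path) {
  x <- jsonlite::fromJSON(path)
  methods::new("LabelSpace", contexts = as.character(x$contexts),
               counts = as.integer(x$counts))
}

# Context key per variation row of a dataset (vectorized over rows).
.variationContextKeys <- function(v, curated) {
  vapply(seq_len(nrow(v)), function(i) {
    sp <- data.frame(
      smiles = .splitDot(v$species_smiles[i])[[1]],
      role = .splitSemi(v$species_roles[i])[[1]],
      stringsAsFactors = FALSE)
    buildContextKey(assignRoles(sp, curated))
  }, "")
}

#' Filter reaction data and build the training tables
#'
#' Applies the data-processing pipeline: (1) drop variations with yield
#' below \code{minYield}; (2) count context usage over the survivors and
#' keep only the \code{k} most common contexts (the \code{LabelSpace});
#' (3) collapse to unique reactions (identical canonical reactants and
#' product) and build the single-label table, keeping per reaction the
#' surviving variation with the highest yield (ties: earliest date, then
#' lowest context index), weighted by yield/100; (4) build the multi-label
#' table whose label vector is the bitwise-or of the one-hot vectors of all
#' distinct surviving contexts of the reaction, weight 1; duplicate
#' (reaction, context) pairs contribute once.
#'
#' @param ds a \code{ReactionDataset}.
#' @param k number of contexts to keep (default 30).
#' @param minYield minimum percent yield, inclusive (default 20).
#' @param curated curated role lists for role assignment.
#' @return list with elements \code{labelSpace} (a \code{LabelSpace}),
#'   \code{single} (data.frame: record_id, reactant_smiles, product_smiles,
#'   label, context_key, weight, year), \code{multi} (data.frame:
#'   record_id, reactant_smiles, product_smiles, weight, year),
#'   \code{multiLabels} (binary matrix, one row per multi example), and
#'   \code{report} (stage accounting, see \code{\link{datasetReport}}).
#' @export
filterAndLabel <- function(ds, k = 30, minYield = 20,
                           curated = curatedLists()) {
  stopifnot(methods::is(ds, "ReactionDataset"), k >= 1,
            minYield >= 0, minYield <= 100)
  v <- variations(ds)
  if (nrow(v) == 0) stop("dataset is empty", call. = FALSE)
  n_in <- nrow(v)
  records_in <- length(unique(v$record_id))

  v$year <- as.integer(substr(v$date, 1, 4))
  v$context_key <- .variationContextKeys(v, curated)

  keep_yield <- v$yield_percent >= minYield
  dropped_yield <- sum(!keep_yield)
  v <- v[keep_yield, , drop = FALSE]

  if (nrow(v) == 0) {
    ls <- methods::new("LabelSpace", contexts = character(0),
                       counts = integer(0))
    empty <- data.frame(record_id = character(0),
                        reactant_smiles = character(0),
                        product_smiles = character(0))
    report <- list(
      variations = c(input = n_in, dropped_yield = dropped_yield,
                     dropped_rare_context = 0L, kept = 0L),
      records = c(input = records_in, kept = 0L, dropped = records_in),
      unique_reactions = 0L,
      record_context_counts = c(`1` = 0L, `2` = 0L, `3+` = 0L),
      record_context_proportions = c(`1` = 0, `2` = 0, `3+` = 0),
      context_counts = integer(0))
    return(list(labelSpace = ls, single = empty, multi = empty,
                multiLabels = matrix(0L, 0, 0), report = report))
  }

  tab <- table(v$context_key)
  ord <- order(-as.integer(tab), names(tab))
  n_distinct <- length(tab)
  if (k > n_distinct) {
    warning("only ", n_distinct, " distinct contexts present; ",
            "label space truncated to ", n_distinct)
    k <- n_distinct
  }
  keys <- names(tab)[ord][seq_len(k)]
  ls <- methods::new("LabelSpace", contexts = keys,
                     counts = as.integer(tab)[ord][seq_len(k)])

  keep_ctx <- v$context_key %in% keys
  dropped_rare <- sum(!keep_ctx)
  v <- v[keep_ctx, , drop = FALSE]
  v$label <- match(v$context_key, keys)
  v$rxn <- paste(v$reactant_smiles, v$product_smiles, sep = ">>")

  records_kept <- length(unique(v$record_id))

  groups <- split(v, factor(v$rxn, levels = unique(v$rxn)))
  single <- do.call(rbind, lapply(groups, function(g) {
    o <- order(-g$yield_percent, g$date, g$label)
    g[o[1], c("record_id", "reactant_smiles", "product_smiles", "label",
              "context_key", "yield_percent", "year")]
  }))
  rownames(single) <- NULL
  single$weight <- single$yield_percent / 100
  single$yield_percent <- NULL

  multi <- do.call(rbind, lapply(groups, function(g) {
    data.frame(record_id = g$record_id[1],
               reactant_smiles = g$reactant_smiles[1],
               product_smiles = g$product_smiles[1],
               weight = 1, year = min(g$year),
               labels = I(list(sort(unique(g$label)))),
               stringsAsFactors = FALSE)
  }))
  rownames(multi) <- NULL
  Y <- matrix(0L, nrow(multi), k)
  for (i in seq_len(nrow(multi))) Y[i, multi$labels[[i]]] <- 1L
  multi$labels <- NULL

  # per-record distinct surviving context counts (for the report)
  per_rec <- tapply(v$context_key, v$record_id,
                    function(x) length(unique(x)))
  nctx <- c(`1` = sum(per_rec == 1), `2` = sum(per_rec == 2),
            `3+` = sum(per_rec >= 3))

  report <- list(
    variations = c(input = n_in, dropped_yield = dropped_yield,
                   dropped_rare_context = dropped_rare, kept = nrow(v)),
    records = c(input = records_in, kept = records_kept,
                dropped = records_in - records_kept),
    unique_reactions = nrow(single),
    record_context_counts = nctx,
    record_context_proportions = if (records_kept > 0) nctx / records_kept
                                 else nctx,
    context_counts = stats::setNames(ls@counts, ls@contexts))

  list(labelSpace = ls, single = single, multi = multi, multiLabels = Y,
       report = report)
}

#' Summarize a dataset's filtering and context usage
#'
#' Runs the filtering pipeline and returns its stage accounting: variation
#' counts dropped at the yield and rare-context stages (conserving the
#' input total), record counts in/kept/dropped, the proportions of kept
#' records with 1, 2 and 3+ distinct surviving contexts, and the
#' per-context usage counts underlying the label space.
#'
#' @inheritParams filterAndLabel
#' @return a list as described above.
#' @export
datasetReport <- function(ds, k = 30, minYield = 20,
                          curated = curatedLists()) {
  filterAndLabel(ds, k = k, minYield = minYield, curated = curated)$report
}

#' One-hot encode single-label assignments
#'
#' @param labels integer label indices (1-based).
#' @param k number of labels.
#' @return binary matrix, \code{length(labels)} x \code{k}.
#' @export
oneHot <- function(labels, k) {
  stopifnot(all(labels >= 1), all(labels <= k))
  m <- matrix(0L, length(labels), k)
  m[cbind(seq_along(labels), labels)] <- 1L
  m
}
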