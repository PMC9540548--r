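# Reaction difference fingerprints.
#
# Per-molecule input is a 1024-bit binary vector: the first 512 bits are a
# folded radius-3 circular (extended-connectivity) fingerprint, the last 512
# a folded linear-path fingerprint (paths up to 7 atoms). The reaction
# fingerprint is the integer difference fp(product) - sum(fp(reactants));
# the sign separates substructure environments gained in the product from
# those lost from the reactants. Context species never enter the reaction
# fingerprint.

.obVersion <- function() {
  if (is.null(.bh_cache$ob_version)) {
    out <- suppressWarnings(system2(.obabel(), "-V", stdout = TRUE,
                                    stderr = FALSE))
    .bh_cache$ob_version <- trimws(sub("--.*$", "", out[1]))
  }
  .bh_cache$ob_version
}

#' Fingerprint configuration
#'
#' Captures everything that determines bit identities, so downstream models
#' can refuse inputs featurized under a different configuration.
#'
#' @param chirality keep stereochemistry annotations when fingerprinting
#'   (default \code{FALSE}: molecules are stereo-stripped first).
#' @return named list: circular/path fingerprint types and folded lengths,
#'   chirality flag and toolkit version string.
#' @export
fpConfig <- function(chirality = FALSE) {
  list(circular = "ECFP6", circularBits = 512L,
       path = "FP2", pathBits = 512L,
       chirality = chirality, toolkit = .obVersion())
}

# Decode FPS hex strings (all the same length) into a 0/1 integer matrix.
.hexToBits <- function(hex) {
  n <- length(hex)
  nhex <- nchar(hex[1])
  vals <- c(0:9, 10:15, 10:15)
  names(vals) <- c(0:9, letters[1:6], LETTERS[1:6])
  v <- matrix(vals[unlist(strsplit(hex, ""), use.names = FALSE)],
              nrow = n, byrow = TRUE)
  nbits <- nhex * 4L
  res <- matrix(0L, n, nbits)
  masks <- c(8L, 4L, 2L, 1L)
  for (k in 1:4)
    res[, seq(k, nbits, by = 4L)] <-
      as.integer(bitwAnd(v, masks[k]) > 0L)
  res
}

# Raw toolkit fingerprints for a batch of SMILES (rows align with input).
.obFingerprintBits <- function(smiles, fptype) {
  out <- .runObabel(smiles, c("-ofps", paste0("-xf", fptype)))
  idx <- as.integer(names(out))
  if (length(idx) < length(smiles)) {
    bad <- smiles[setdiff(seq_along(smiles), idx)]
    stop("cannot fingerprint SMILES: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  bits <- .hexToBits(out)
  bits[order(idx), , drop = FALSE]
}

# OR-fold a wide bit matrix down to `bits` columns.
.foldBits <- function(mat, bits) {
  stopifnot(ncol(mat) %% bits == 0)
  out <- matrix(0L, nrow(mat), bits)
  for (j in seq_len(ncol(mat) / bits))
    out <- out | mat[, ((j - 1) * bits + 1):(j * bits), drop = FALSE]
  mode(out) <- "integer"
  out
}

#' Per-molecule hashed fingerprint
#'
#' 1024 binary entries: folded radius-3 circular bits (1-512) concatenated
#' with folded linear-path bits (513-1024). Deterministic for a fixed
#' toolkit version; results are memoised per canonical SMILES for the
#' session.
#'
#' @param smiles character vector of SMILES.
#' @param config fingerprint configuration from \code{\link{fpConfig}}.
#' @return integer 0/1 matrix, one row per input molecule, 1024 columns.
#' @export
moleculeFingerprint <- function(smiles, config = fpConfig()) {
  can <- canonicalizeSmiles(smiles, stripStereo = !isTRUE(config$chirality))
  ckey <- paste0("fp:", config$circular, config$path,
                 as.integer(isTRUE(config$chirality)), ":", can)
  out <- matrix(0L, length(can), config$circularBits + config$pathBits)
  hit <- vapply(ckey, function(k) !is.null(.bh_cache[[k]]), TRUE,
                USE.NAMES = FALSE)
  for (i in which(hit)) out[i, ] <- .bh_cache[[ckey[i]]]
  todo <- which(!hit)
  if (length(todo)) {
    uq <- unique(can[todo])
    circ <- .foldBits(.obFingerprintBits(uq, config$circular),
                      config$circularBits)
    path <- .foldBits(.obFingerprintBits(uq, config$path), config$pathBits)
    fp <- cbind(circ, path)
    rows <- match(can[todo], uq)
    out[todo, ] <- fp[rows, , drop = FALSE]
    for (i in todo) .bh_cache[[ckey[i]]] <- out[i, ]
  }
  out
}

#' Reaction difference fingerprint
#'
#' \code{fp(product) - sum(fp(reactant_i))} in integer arithmetic. With
#' binary per-molecule fingerprints every entry lies in [-R, 1] where R is
#' the number of reactants; the all-zero vector arises exactly when product
#' and reactants share all fingerprint bits (e.g. an identity reaction).
#'
#' @param reactants character vector of reactant SMILES (>= 1).
#' @param product single product SMILES.
#' @param config fingerprint configuration.
#' @return integer vector of length 1024.
#' @export
reactionFingerprint <- function(reactants, product, config = fpConfig()) {
  stopifnot(length(reactants) >= 1, length(product) == 1)
  fps <- moleculeFingerprint(c(reactants, product), config)
  n <- length(reactants)
  prod_fp <- fps[n + 1L, ]
  react_sum <- if (n == 1) fps[1L, ] else colSums(fps[seq_len(n), , drop = FALSE])
  as.integer(prod_fp - react_sum)
}

#' Featurize a table of reactions
#'
#' Computes the difference fingerprint for every row of a training table
#' (columns \code{reactant_smiles}, dot-separated, and
#' \code{product_smiles}). All unique molecules are fingerprinted in one
#' batched toolkit call.
#'
#' @param table data.frame with \code{reactant_smiles} and
#'   \code{product_smiles} columns (e.g. from \code{\link{filterAndLabel}}).
#' @param config fingerprint configuration.
#' @return integer matrix, one row per reaction, 1024 columns, with the
#'   configuration attached as attribute \code{"fpConfig"}.
#' @export
featurizeReactions <- function(table, config = fpConfig()) {
  stopifnot(all(c("reactant_smiles", "product_smiles") %in% names(table)))
  react <- .splitDot(table$reactant_smiles)
  mols <- unique(c(unlist(react), table$product_smiles))
  fps <- moleculeFingerprint(mols, config)
  rownames(fps) <- mols
  X <- t(vapply(seq_len(nrow(table)), function(i) {
    r <- react[[i]]
    rs <- if (length(r) == 1) fps[r, ] else colSums(fps[r, , drop = FALSE])
    as.integer(fps[table$product_smiles[i], ] - rs)
  }, integer(ncol(fps))))
  attr(X, "fpConfig") <- config
  X
}

#' Persist / load a featurized matrix with its configuration sidecar
#'
#' The matrix is written as a dense CSV and the fingerprint configuration
#' as a JSON sidecar (\code{<path>.json}); \code{readFeatures} refuses a
#' matrix whose sidecar is missing.
#'
#' @param X featurized matrix from \code{\link{featurizeReactions}}.
#' @param path output CSV path.
#' @return \code{readFeatures}: the matrix with \code{"fpConfig"} attached.
#' @export
writeFeatures <- function(X, path) {
  config <- attr(X, "fpConfig")
  if (is.null(config)) stop("matrix lacks an fpConfig attribute")
  utils::write.table(X, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing fingerprint-config sidecar: ", sidecar, call. = FALSE)
  X <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(X) <- NULL
  mode(X) <- "integer"
  cfg <- jsonlite::fromJSON(sidecar)
  cfg$circularBits <- as.integer(cfg$circularBits)
  cfg$pathBits <- as.integer(cfg$pathBits)
  attr(X, "fpConfig") <- cfg
  X
}
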