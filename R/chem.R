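# SMILES handling on top of OpenBabel (obabel CLI). All heavy calls are
# batched: one obabel invocation per unique set of input strings, results
# memoised in a package-level cache for the session.

.bh_cache <- new.env(parent = emptyenv())

.obabel <- function() {
  path <- Sys.which("obabel")
  if (!nzchar(path))
    stop("OpenBabel executable 'obabel' not found on PATH; it is required ",
         "for SMILES canonicalization and fingerprinting.", call. = FALSE)
  path
}

#' Quick syntactic screen for SMILES strings
#'
#' OpenBabel silently repairs some malformed inputs (an unclosed branch such
#' as \code{"C("} parses as \code{"C"}), so structurally broken strings are
#' rejected before they reach the toolkit: unbalanced parentheses or
#' brackets, unmatched ring-closure digits, empty strings and characters
#' outside the SMILES alphabet.
#'
#' @param smiles character vector.
#' @return logical vector, \code{TRUE} where the string passes the screen.
#' @keywords internal
.smilesSyntaxOk <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\.%*]", s)) return(FALSE)
    chars <- strsplit(s, "")[[1]]
    if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
    if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
    # ring closures: strip bracket atoms (isotope digits live there), then
    # every digit (and %nn pair) must occur an even number of times
    bare <- gsub("\\[[^]]*\\]", "[]", s)
    ring <- c(regmatches(bare, gregexpr("%[0-9]{2}", bare))[[1]],
              regmatches(gsub("%[0-9]{2}", "", bare),
                         gregexpr("[0-9]", gsub("%[0-9]{2}", "", bare)))[[1]])
    if (length(ring) && any(table(ring) %% 2 != 0)) return(FALSE)
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# Run obabel over a batch of SMILES, returning the per-molecule output lines
# keyed by input index; molecules obabel could not parse are absent.
.runObabel <- function(smiles, outArgs) {
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile()
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(smiles, paste0("bhid", seq_along(smiles))), infile)
  status <- suppressWarnings(system2(
    .obabel(), c(shQuote(infile), outArgs, "-O", shQuote(outfile), "-e"),
    stdout = FALSE, stderr = FALSE))
  if (!file.exists(outfile)) return(character(0))
  lines <- readLines(outfile, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vals <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(parts, function(p) trimws(p[[length(p)]]), "")
  keep <- grepl("^bhid[0-9]+$", ids)
  structure(vals[keep], names = sub("^bhid", "", ids[keep]))
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form, the identity used throughout
#' the package for molecules and context species. Canonicalization is
#' idempotent: \code{canonicalizeSmiles(canonicalizeSmiles(s)) ==
#' canonicalizeSmiles(s)}.
#'
#' @param smiles character vector of SMILES.
#' @param stripStereo drop stereochemistry annotations (wedge bonds
#'   \code{/}, \code{\\} and \code{@} chirality) before canonicalization.
#'   Default \code{FALSE}: stereochemistry is retained.
#' @param mustWork if \code{TRUE} (default) an unparseable string is an
#'   error naming the offending input(s); if \code{FALSE} it yields
#'   \code{NA}.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalizeSmiles(c("OCC", "CCO"))      # identical output
#' canonicalizeSmiles("C1=CC=CC=C1")        # "c1ccccc1"
#' }
#' @export
canonicalizeSmiles <- function(smiles, stripStereo = FALSE, mustWork = TRUE) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  query <- smiles
  if (stripStereo)
    query <- gsub("@", "", gsub("[/\\\\]", "", query))
  key <- paste0("can:", as.integer(stripStereo), ":", query)
  out <- rep(NA_character_, length(smiles))
  cached <- vapply(key, function(k) {
    if (!is.null(.bh_cache[[k]])) .bh_cache[[k]] else NA_character_
  }, "", USE.NAMES = FALSE)
  out[!is.na(cached)] <- cached[!is.na(cached)]
  todo <- which(is.na(out))
  if (length(todo)) {
    uq <- unique(query[todo])
    ok <- .smilesSyntaxOk(uq)
    res <- rep(NA_character_, length(uq))
    if (any(ok)) {
      conv <- .runObabel(uq[ok], "-ocan")
      idx <- as.integer(names(conv))
      res[which(ok)[idx]] <- unname(conv)
    }
    names(res) <- uq
    out[todo] <- res[query[todo]]
    done <- !is.na(out[todo])
    for (i in todo[done]) .bh_cache[[key[i]]] <- out[i]
  }
  if (mustWork && anyNA(out)) {
    bad <- unique(smiles[is.na(out)])
    stop("unparseable SMILES: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Test whether SMILES strings are valid
#'
#' @param smiles character vector.
#' @return logical vector; \code{TRUE} where the string parses.
#' @export
validSmiles <- function(smiles) {
  !is.na(canonicalizeSmiles(smiles, mustWork = FALSE))
}

#' Does a species contain palladium or platinum?
#'
#' Pd and Pt only ever appear as bracket atoms in SMILES, so a pattern match
#' suffices; used by the role-assignment fallback that flags any Pd- or
#' Pt-containing species as a catalyst.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
containsPdPt <- function(smiles) {
  grepl("\\[[0-9]*(Pd|Pt)", smiles)
}
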