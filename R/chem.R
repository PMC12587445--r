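# Low-level chemistry helpers on top of ChemmineOB (OpenBabel).
#
# All structures are handled as SMILES and parsed per molecule with
# OpenBabel; no SDF round-trip is involved, so single-atom molecules and
# ions behave like any other structure. Unparseable SMILES are detected up
# front (OpenBabel aborts batch iteration when it hits one).

# Batch-validate SMILES. Returns a logical vector aligned with `smiles`.
ob_valid_smiles <- function(smiles) {
  if (length(smiles) == 0) return(logical(0))
  ids <- sprintf("m%06d", seq_along(smiles))
  ok0 <- !is.na(smiles) & nzchar(smiles)
  txt <- paste0(smiles[ok0], "\t", ids[ok0], "\n", collapse = "")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", txt),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  seen <- vapply(strsplit(lines, "\t", fixed = TRUE), function(x) {
    if (length(x) >= 2) trimws(x[2]) else ""
  }, character(1))
  ids %in% seen
}

# Parse each SMILES with OpenBabel and apply `fn` to the molecule object.
# Input must be a named character vector; unparseable entries raise an
# error naming the chemical. Returns a named list aligned with the input.
ob_apply <- function(smiles, fn) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  if (is.null(names(smiles))) names(smiles) <- sprintf("cmp%05d", seq_along(smiles))
  ok <- ob_valid_smiles(smiles)
  if (any(!ok)) {
    stop("unparseable SMILES for: ", paste(names(smiles)[!ok], collapse = ", "))
  }
  txt <- paste0(smiles, "\t", names(smiles), "\n", collapse = "")
  res <- ChemmineOB::forEachMol("SMILES", txt, fn)
  names(res) <- names(smiles)
  res
}

# OpenBabel property block (canonical SMILES with/without stereo, formula,
# MW, logP, TPSA, HB donor/acceptor counts, ...) for a SMILES batch.
ob_properties <- function(smiles) {
  rows <- ob_apply(smiles, ChemmineOB::prop_OB)
  p <- do.call(rbind, lapply(rows, as.data.frame))
  p$cid <- names(rows)
  rownames(p) <- NULL
  p
}

# Count unique SMARTS matches per molecule of a SMILES batch.
ob_smarts_count <- function(smiles, smarts) {
  res <- ob_apply(smiles, function(m) {
    as.numeric(ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE))
  })
  unlist(res)
}

# Batch-canonicalize SMILES with OpenBabel. Returns NA where conversion
# fails; works for single atoms and ions.
ob_canonical <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  ok <- ob_valid_smiles(smiles)
  if (!any(ok)) return(out)
  ids <- sprintf("m%06d", which(ok))
  txt <- paste0(smiles[ok], "\t", ids, "\n", collapse = "")
  res <- ChemmineOB::convertFormat("SMI", "CAN", txt)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, character(1), 1)
  nm <- trimws(vapply(parts, function(x) if (length(x) >= 2) x[2] else "",
                      character(1)))
  hit <- nm %in% ids
  out[which(ok)[match(nm[hit], ids)]] <- can[hit]
  out
}

# Remove stereochemical annotations from a SMILES string (tetrahedral @ /
# @@ marks and cis/trans bond slashes); the result is re-canonicalized by
# the caller.
strip_stereo_smiles <- function(smiles) {
  s <- gsub("@", "", smiles, fixed = TRUE)
  gsub("[/\\\\]", "", s)
}

# Count heavy atoms and carbons by tokenizing a SMILES component: bracket
# atoms first, then the organic-subset symbols outside brackets.
count_atoms_smiles <- function(smi) {
  brackets <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1]]
  elem_b <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", brackets)
  rest <- gsub("\\[[^]]*\\]", "", smi)
  elem_o <- regmatches(rest, gregexpr("Cl|Br|[BCNOPSFI]|[bcnops]", rest))[[1]]
  elems <- c(elem_b, elem_o)
  norm <- ifelse(elems %in% c("c", "n", "o", "p", "s", "b"),
                 toupper(elems), elems)
  c(n_heavy = sum(norm != "H"), n_carbon = sum(norm == "C"))
}
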