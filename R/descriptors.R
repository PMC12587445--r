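# Descriptor sets: circular fingerprints, MACCS keys, a physicochemical
# panel, and the hydrogen-bonding / polar-surface properties used by the
# brain-exposure score.

#' The frozen physicochemical descriptor panel
#'
#' Names of the columns produced by [compute_physchem()], frozen so that
#' descriptor matrices are reproducible across toolkit upgrades. The panel
#' mixes whole-molecule properties (molecular weight, logP, molar
#' refractivity, topological polar surface area, hydrogen-bond counts) with
#' counts of atoms, bonds, rings and common functional groups obtained by
#' SMARTS matching.
#'
#' @return character vector of feature names.
#' @export
physchem_panel <- function() {
  c("mw", "logp", "mr", "tpsa", "hbd", "hba",
    "n_heavy", "n_bonds", "n_rings", "n_rotatable",
    "n_aromatic_atoms", "frac_aromatic", "n_ring_atoms",
    "n_carbon", "n_nitrogen", "n_oxygen", "n_sulfur",
    "n_halogen", "n_fluorine", "n_heteroatoms",
    "n_sp3_carbon", "frac_csp3",
    "n_hydroxyl", "n_carbonyl", "n_amide", "n_carboxyl",
    "n_tertiary_amine", "n_charged")
}

# SMARTS definitions backing the count features of the panel
PHYSCHEM_SMARTS <- c(
  n_heavy = "[!#1]",
  n_bonds = "*~*",
  n_rotatable = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
  n_aromatic_atoms = "[a]",
  n_ring_atoms = "[R]",
  n_carbon = "[#6]",
  n_nitrogen = "[#7]",
  n_oxygen = "[#8]",
  n_sulfur = "[#16]",
  n_halogen = "[F,Cl,Br,I]",
  n_fluorine = "[F]",
  n_heteroatoms = "[!#6;!#1]",
  n_sp3_carbon = "[CX4]",
  n_hydroxyl = "[OX2H]",
  n_carbonyl = "[CX3]=[OX1]",
  n_amide = "[NX3][CX3](=[OX1])",
  n_carboxyl = "[CX3](=O)[OX2H1]",
  n_tertiary_amine = "[NX3]([#6])([#6])[#6]",
  n_charged = "[+1,-1,+2,-2]"
)

#' Compute binary fingerprints (circular ECFP6 or MACCS keys)
#'
#' `ECFP6_1024`: extended-connectivity fingerprint with bond radius 3
#' (diameter-6 convention), folded by bitwise OR from OpenBabel's 4096-bit
#' representation down to 1024 bits. `MACCS_166`: the 166 public MACCS
#' substructure keys. Rows depend only on the structures, not on input
#' order; identical canonical SMILES give identical bit rows.
#'
#' @param smiles character vector of (preferably standardized) SMILES;
#'   names, when present, become row names.
#' @param set `"ECFP6_1024"` or `"MACCS_166"`.
#' @return integer 0/1 matrix, chemicals x bits, with named columns.
#' @export
#' @examples
#' fp <- compute_fingerprint(c(etoh = "CCO", benzene = "c1ccccc1"), "MACCS_166")
#' dim(fp)  # 2 x 166
compute_fingerprint <- function(smiles, set = c("ECFP6_1024", "MACCS_166")) {
  set <- match.arg(set)
  smiles <- ensure_names(smiles)
  type <- if (set == "MACCS_166") "MACCS" else "ECFP6"
  rows <- ob_apply(smiles, function(m) {
    as.numeric(ChemmineOB::fingerprint_OB(list(m), type))
  })
  raw <- do.call(rbind, rows)
  if (set == "MACCS_166") {
    m <- raw[, seq_len(166), drop = FALSE]
    colnames(m) <- sprintf("MACCS_%03d", seq_len(166))
  } else {
    stopifnot(ncol(raw) == 4096)
    m <- matrix(0L, nrow(raw), 1024)
    for (k in 0:3) m <- m | raw[, k * 1024 + seq_len(1024), drop = FALSE]
    colnames(m) <- sprintf("ECFP6_%04d", seq_len(1024))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- names(smiles)
  m
}

#' Compute the physicochemical descriptor panel
#'
#' Produces the fixed, named panel of [physchem_panel()] for each structure.
#' Whole-molecule properties come from OpenBabel; group counts come from
#' SMARTS matching; ring count is the cyclomatic number (bonds - atoms + 1)
#' of the connected, standardized structure. Non-finite entries are left as
#' NA here and imputed with training-fold medians inside the modeling step.
#'
#' @param smiles character vector of SMILES (names become row names).
#' @return numeric matrix, chemicals x `length(physchem_panel())`.
#' @export
compute_physchem <- function(smiles) {
  smiles <- ensure_names(smiles)
  rows <- ob_apply(smiles, function(mol) {
    p <- ChemmineOB::prop_OB(mol)
    counts <- vapply(PHYSCHEM_SMARTS, function(s) {
      as.numeric(ChemmineOB::smartsSearch_OB(list(mol), s, uniqueMatches = TRUE))
    }, numeric(1))
    c(mw = as.numeric(p$MW), logp = as.numeric(p$logP),
      mr = as.numeric(p$MR), tpsa = as.numeric(p$TPSA),
      hbd = as.numeric(p$HBD), hba = as.numeric(p$HBA2), counts)
  })
  raw <- do.call(rbind, rows)
  m <- matrix(NA_real_, length(smiles), length(physchem_panel()),
              dimnames = list(names(smiles), physchem_panel()))
  m[, colnames(raw)] <- raw
  # cyclomatic ring count of the (connected, standardized) structure
  m[, "n_rings"] <- pmax(m[, "n_bonds"] - m[, "n_heavy"] + 1, 0)
  m[, "frac_aromatic"] <- m[, "n_aromatic_atoms"] / pmax(m[, "n_heavy"], 1)
  m[, "frac_csp3"] <- m[, "n_sp3_carbon"] / pmax(m[, "n_carbon"], 1)
  m
}

#' Compute the brain-exposure physicochemical properties
#'
#' Topological polar surface area (Ertl contribution method as implemented
#' in OpenBabel), hydrogen-bond donor count and hydrogen-bond acceptor
#' count for each structure.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns `chemical_id`, `tpsa`, `hbd`, `hba`.
#' @export
#' @examples
#' compute_brain_props(c(ethanol = "CCO"))  # tpsa 20.23, hbd 1, hba 1
compute_brain_props <- function(smiles) {
  smiles <- ensure_names(smiles)
  props <- ob_properties(smiles)
  data.frame(chemical_id = props$cid,
             tpsa = props$TPSA,
             hbd = as.integer(props$HBD),
             hba = as.integer(props$HBA2),
             stringsAsFactors = FALSE)
}

#' Tanimoto similarity of two bit vectors
#'
#' \eqn{|a \wedge b| / |a \vee b|}, defined as 0 when both vectors are
#' all-zero.
#'
#' @param a,b equal-length binary vectors.
#' @return similarity in \[0, 1\].
#' @export
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Pairwise Tanimoto similarities between two fingerprint matrices
#'
#' @param A,B binary matrices with the same number of columns.
#' @return `nrow(A)` x `nrow(B)` similarity matrix.
#' @export
tanimoto_matrix <- function(A, B) {
  A <- matrix(as.numeric(A != 0), nrow(A)); B <- matrix(as.numeric(B != 0), nrow(B))
  stopifnot(ncol(A) == ncol(B))
  inter <- A %*% t(B)
  union <- outer(rowSums(A), rowSums(B), `+`) - inter
  sim <- ifelse(union == 0, 0, inter / union)
  sim
}

#' Look up MACCS key substructure descriptions
#'
#' Descriptions are read from the MACCS SMARTS definition file shipped with
#' the installed OpenBabel distribution; when that file cannot be located
#' the generic description "MACCS key N" is returned.
#'
#' @param keys integer vector of key numbers (1-166).
#' @return character vector of descriptions.
#' @export
maccs_key_description <- function(keys) {
  defs <- maccs_definitions()
  out <- sprintf("MACCS key %d", keys)
  if (!is.null(defs)) {
    m <- match(keys, defs$key)
    hit <- !is.na(m)
    out[hit] <- sprintf("MACCS key %d: %s [%s]", keys[hit],
                        defs$comment[m[hit]], defs$smarts[m[hit]])
  }
  out
}

# Parse OpenBabel's MACCS.txt ("N:('SMARTS',count), # comment") if present.
maccs_definitions <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ob <- Sys.which("obabel")
    if (!nzchar(ob)) return(NULL)
    root <- file.path(dirname(dirname(ob)), "share", "openbabel")
    files <- list.files(root, pattern = "^MACCS\\.txt$", recursive = TRUE,
                        full.names = TRUE)
    if (!length(files)) return(NULL)
    lines <- readLines(files[1], warn = FALSE)
    m <- regmatches(lines,
                    regexec("^\\s*(\\d+):\\('([^']*)',(\\d+)\\),?\\s*#*\\s*(.*)$",
                            lines))
    rows <- Filter(function(x) length(x) == 5, m)
    if (!length(rows)) return(NULL)
    cache <<- data.frame(
      key = as.integer(vapply(rows, `[`, character(1), 2)),
      smarts = vapply(rows, `[`, character(1), 3),
      comment = trimws(vapply(rows, `[`, character(1), 5)),
      stringsAsFactors = FALSE
    )
    cache
  }
})

# give unnamed SMILES vectors stable names (preserving existing ones)
ensure_names <- function(smiles) {
  nm <- names(smiles)
  smiles <- as.character(smiles)
  names(smiles) <- nm
  if (is.null(nm) || any(!nzchar(nm))) {
    names(smiles) <- sprintf("cmp%05d", seq_along(smiles))
  }
  smiles
}
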