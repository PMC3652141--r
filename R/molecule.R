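#' Parse a SMILES string into a molecule object
#'
#' Reads a (Daylight) SMILES string through Open Babel, resolving aromatic
#' perception and implicit hydrogens, and returns a light-weight molecular
#' graph: heavy atoms with element, formal charge and attached-hydrogen count,
#' and heavy-atom bonds with order and ring membership. This graph is the input
#' to all descriptor calculations.
#'
#' @param smiles A single non-empty SMILES string.
#' @param identifier Label carried along into descriptor records; defaults to
#'   the SMILES string itself.
#' @return An object of class `"molecule"`: a list with elements `identifier`,
#'   `smiles`, `atoms` (data frame: `element`, `charge`, `n_h`), `bonds`
#'   (data frame: `a1`, `a2`, `order`, `in_ring`) and `sdf` (the underlying
#'   `ChemmineR::SDFset`, explicit hydrogens included).
#' @examples
#' m <- parse_smiles("ClCCN(N=O)C(=O)NC1CCCCC1", "lomustine")
#' heavy_atom_count(m)
#' @export
parse_smiles <- function(smiles, identifier = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop_structure("'smiles' must be a single non-empty string")
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles,
                              options = data.frame(names = "h", args = "",
                                                   stringsAsFactors = FALSE)),
    error = function(e) "")
  if (!nzchar(txt) || !grepl("V2000", txt, fixed = TRUE))
    stop_structure("could not parse SMILES: '", smiles, "'")
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(unlist(strsplit(txt, "\n", fixed = TRUE)))),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) < 1L)
    stop_structure("could not parse SMILES: '", smiles, "'")
  mol_from_sdf(sdf, smiles = smiles, identifier = identifier, sdf_text = txt)
}

# Build the heavy-atom graph from an explicit-hydrogen SDF.
mol_from_sdf <- function(sdf, smiles, identifier, sdf_text) {
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- gsub("_.*$", "", rownames(ab))
  n_all <- length(elements)
  charges <- parse_chg_lines(sdf_text, n_all)

  if (n_all >= 2L && nrow(bb) >= 1L) {
    bonds_all <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                            order = as.integer(bb[, 3]))
  } else {
    bonds_all <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }

  heavy <- which(elements != "H")
  if (length(heavy) == 0L)
    stop_structure("molecule '", identifier, "' has no heavy atoms")
  idx_map <- integer(n_all)
  idx_map[heavy] <- seq_along(heavy)

  n_h <- integer(length(heavy))
  keep <- logical(nrow(bonds_all))
  for (i in seq_len(nrow(bonds_all))) {
    e1 <- elements[bonds_all$a1[i]]; e2 <- elements[bonds_all$a2[i]]
    if (e1 == "H" && e2 == "H") next
    if (e1 == "H") {
      n_h[idx_map[bonds_all$a2[i]]] <- n_h[idx_map[bonds_all$a2[i]]] + 1L
    } else if (e2 == "H") {
      n_h[idx_map[bonds_all$a1[i]]] <- n_h[idx_map[bonds_all$a1[i]]] + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  bonds <- bonds_all[keep, , drop = FALSE]
  bonds$a1 <- idx_map[bonds$a1]
  bonds$a2 <- idx_map[bonds$a2]
  rownames(bonds) <- NULL
  bonds$in_ring <- ring_bonds(length(heavy), bonds)

  atoms <- data.frame(element = elements[heavy],
                      charge = charges[heavy],
                      n_h = n_h,
                      stringsAsFactors = FALSE)
  structure(list(identifier = identifier, smiles = smiles,
                 atoms = atoms, bonds = bonds, sdf = sdf),
            class = "molecule")
}

# Formal charges from "M  CHG" property lines of a V2000 molfile.
parse_chg_lines <- function(txt, n_atoms) {
  charges <- integer(n_atoms)
  lines <- grep("^M  CHG", unlist(strsplit(txt, "\n", fixed = TRUE)), value = TRUE)
  for (ln in lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charges[f[2 * j]] <- f[2 * j + 1]
  }
  charges
}

# A bond is in a ring iff it is not a bridge of the molecular graph.
ring_bonds <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(bonds))
  res[as.integer(br)] <- FALSE
  res
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$identifier, "\n", sep = "")
  cat("  SMILES: ", x$smiles, "\n", sep = "")
  cat("  heavy atoms: ", nrow(x$atoms), ", bonds: ", nrow(x$bonds), "\n", sep = "")
  invisible(x)
}

#' Canonical SMILES of a molecule
#'
#' @param m A `molecule`.
#' @return Open Babel canonical SMILES string.
#' @export
canonical_smiles <- function(m) {
  stopifnot(inherits(m, "molecule"))
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = m$smiles)
  trimws(strsplit(out, "\t|\n")[[1]][1])
}

# neighbours of heavy atom i (heavy-atom indices)
mol_neighbors <- function(m, i) {
  b <- m$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# heavy-atom degree vector
mol_degree <- function(m) {
  d <- integer(nrow(m$atoms))
  if (nrow(m$bonds)) {
    t1 <- table(factor(m$bonds$a1, levels = seq_len(nrow(m$atoms))))
    t2 <- table(factor(m$bonds$a2, levels = seq_len(nrow(m$atoms))))
    d <- as.integer(t1 + t2)
  }
  d
}
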