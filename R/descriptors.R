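# Descriptor calculations reproducing the columns of the reference agent
# table: formula weight, heavy-atom count, TPSA (see tpsa.R), H-bond donor /
# acceptor counts, rotatable bonds, and an atom-contribution Log P estimate.

# IUPAC standard atomic weights (abridged) for the elements this chemical
# space can contain; extend as needed.
atomic_weights <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                    Cl = 35.45, Br = 79.904, I = 126.904)

#' Formula weight
#'
#' Sum of standard atomic weights over all atoms, hydrogens included.
#' Full precision is kept internally; reports display one decimal.
#'
#' @param m A [parse_smiles()] molecule.
#' @return Weight in daltons.
#' @examples
#' formula_weight(parse_smiles("ClCCN(N=O)C(=O)NC1CCCCC1"))  # 233.7
#' @export
formula_weight <- function(m) {
  stopifnot(inherits(m, "molecule"))
  unknown <- setdiff(unique(m$atoms$element), names(atomic_weights))
  if (length(unknown))
    stop_input("no atomic weight tabulated for element(s): ",
               paste(unknown, collapse = ", "))
  sum(atomic_weights[m$atoms$element]) +
    atomic_weights[["H"]] * sum(m$atoms$n_h)
}

#' Heavy-atom count
#'
#' @param m A [parse_smiles()] molecule.
#' @return Number of non-hydrogen atoms.
#' @export
heavy_atom_count <- function(m) {
  stopifnot(inherits(m, "molecule"))
  nrow(m$atoms)
}

#' Hydrogen-bond donor and acceptor counts
#'
#' Donors are counted as hydrogens attached to nitrogen or oxygen (so one -OH
#' plus one -NH- gives 2, and water gives 2); acceptors as the total number of
#' nitrogen plus oxygen atoms. These are the conventions behind the "Number of
#' -OH and -NHn" and "Number of O & N" columns of the reference table and the
#' CNS-penetration criteria.
#'
#' @param m A [parse_smiles()] molecule.
#' @return Integer count.
#' @export
hbd_count <- function(m) {
  stopifnot(inherits(m, "molecule"))
  sum(m$atoms$n_h[m$atoms$element %in% c("N", "O")])
}

#' @rdname hbd_count
#' @export
hba_count <- function(m) {
  stopifnot(inherits(m, "molecule"))
  sum(m$atoms$element %in% c("N", "O"))
}

#' Rotatable-bond count
#'
#' Counts acyclic single bonds between two non-terminal heavy atoms, excluding
#' amide C-N bonds (a C-N single bond where the carbon bears a double bond to
#' oxygen). Under this definition lomustine has 4 rotatable bonds: ring-C-N,
#' N-N, N-CH2 and CH2-CH2.
#'
#' @param m A [parse_smiles()] molecule.
#' @return Integer count.
#' @export
rotatable_bond_count <- function(m) {
  stopifnot(inherits(m, "molecule"))
  if (nrow(m$bonds) == 0L) return(0L)
  deg <- mol_degree(m)
  carbonyl_c <- vapply(seq_len(nrow(m$atoms)), function(i) {
    m$atoms$element[i] == "C" && any({
      b <- m$bonds[(m$bonds$a1 == i | m$bonds$a2 == i) & m$bonds$order == 2L, , drop = FALSE]
      other <- ifelse(b$a1 == i, b$a2, b$a1)
      m$atoms$element[other] == "O"
    })
  }, logical(1))
  n <- 0L
  for (i in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a1[i]; b <- m$bonds$a2[i]
    if (m$bonds$order[i] != 1L || m$bonds$in_ring[i]) next
    if (deg[a] < 2L || deg[b] < 2L) next
    ea <- m$atoms$element[a]; eb <- m$atoms$element[b]
    amide <- (ea == "C" && eb == "N" && carbonyl_c[a]) ||
             (eb == "C" && ea == "N" && carbonyl_c[b])
    if (amide) next
    n <- n + 1L
  }
  n
}

#' Octanol-water partition estimate (Log P)
#'
#' Atom-contribution Log P from Open Babel's partition model. This is a
#' documented substitute for the proprietary calculator behind the tabulated
#' reference values, with expected agreement within about one log unit;
#' reproduction statistics always use the tabulated Log P, never this
#' estimate.
#'
#' @param m A [parse_smiles()] molecule.
#' @return Dimensionless Log P estimate.
#' @export
logp_estimate <- function(m) {
  stopifnot(inherits(m, "molecule"))
  p <- ChemmineR::propOB(m$sdf)
  as.numeric(p[1, "logP"])
}

#' Assemble a full descriptor record for one molecule
#'
#' Computes all columns of the reference descriptor set from the structure.
#' `n_ro5_violations` is filled by the screening module's rule; `volume` is
#' omitted (the volume parameterization of the reference calculator is
#' unpublished; fixture volumes come from the embedded table).
#'
#' @param m A [parse_smiles()] molecule.
#' @param logp_override Optional number used verbatim instead of
#'   [logp_estimate()] (e.g. a measured or tabulated value).
#' @return One-row data frame with the descriptor columns.
#' @examples
#' compute_descriptors(parse_smiles("ClCCN(N=O)C(=O)NC1CCCCC1", "lomustine"))
#' @export
compute_descriptors <- function(m, logp_override = NULL) {
  stopifnot(inherits(m, "molecule"))
  log_p <- if (!is.null(logp_override)) {
    if (!is.numeric(logp_override) || length(logp_override) != 1L || !is.finite(logp_override))
      stop_input("logp_override must be a single finite number")
    as.numeric(logp_override)
  } else logp_estimate(m)
  rec <- data.frame(agent_id = m$identifier,
                    log_p = log_p,
                    psa = tpsa(m),
                    n_atoms = heavy_atom_count(m),
                    fw = formula_weight(m),
                    n_on = hba_count(m),
                    n_ohnh = hbd_count(m),
                    n_rot = rotatable_bond_count(m),
                    stringsAsFactors = FALSE)
  rec$n_ro5_violations <- rule_of_five_violations(rec)
  rec[, c("agent_id", "log_p", "psa", "n_atoms", "fw", "n_on", "n_ohnh",
          "n_ro5_violations", "n_rot")]
}
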