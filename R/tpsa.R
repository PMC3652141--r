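#' Ertl fragment contributions for topological polar surface area
#'
#' The published per-environment surface contributions (in squared Angstroms)
#' for neutral nitrogen and oxygen atoms. An atom environment is keyed by
#' element, attached-hydrogen count, the counts of single/double/triple bonds
#' to heavy atoms, and membership in a three-membered ring. Only N and O
#' contribute, matching the convention of the property calculator behind the
#' reference table (sulfur and phosphorus contribute zero there: the
#' sulfanylidene-bearing agent keeps PSA 61.77).
#'
#' @return Data frame with columns `element`, `n_h`, `n_single`, `n_double`,
#'   `n_triple`, `in_ring3`, `contribution`.
#' @export
tpsa_contributions <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
element n_h n_single n_double n_triple in_ring3 contribution
N 0 3 0 0 FALSE  3.24
N 0 3 0 0 TRUE   3.01
N 0 1 1 0 FALSE 12.36
N 0 0 0 1 FALSE 23.79
N 0 1 2 0 FALSE 11.68
N 0 0 1 1 FALSE 13.60
N 1 2 0 0 FALSE 12.03
N 1 2 0 0 TRUE  21.94
N 1 0 1 0 FALSE 23.85
N 2 1 0 0 FALSE 26.02
O 0 2 0 0 FALSE  9.23
O 0 2 0 0 TRUE  12.53
O 0 0 1 0 FALSE 17.07
O 1 1 0 0 FALSE 20.23
")
}

# atoms that are members of a 3-membered ring: two neighbours bonded together
in_three_ring <- function(m) {
  n <- nrow(m$atoms)
  res <- logical(n)
  if (nrow(m$bonds) == 0L) return(res)
  adj <- matrix(FALSE, n, n)
  adj[cbind(m$bonds$a1, m$bonds$a2)] <- TRUE
  adj[cbind(m$bonds$a2, m$bonds$a1)] <- TRUE
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    if (length(nb) >= 2L) {
      pairs <- utils::combn(nb, 2)
      res[i] <- any(adj[cbind(pairs[1, ], pairs[2, ])])
    }
  }
  res
}

#' Topological polar surface area (Ertl fragment method)
#'
#' Sums the published fragment contributions of all nitrogen and oxygen
#' environments in the molecule. Environments without a tabulated contribution
#' (e.g. charged atoms) contribute zero and raise a warning.
#'
#' @param m A [parse_smiles()] molecule.
#' @param breakdown If `TRUE`, also return the per-atom contributions.
#' @return The TPSA in squared Angstroms, or (with `breakdown = TRUE`) a list
#'   with `tpsa` and a per-atom `contributions` data frame.
#' @examples
#' tpsa(parse_smiles("ClCCN(N=O)C(=O)NC1CCCCC1"))  # 61.77
#' @export
tpsa <- function(m, breakdown = FALSE) {
  stopifnot(inherits(m, "molecule"))
  tab <- tpsa_contributions()
  ring3 <- in_three_ring(m)
  polar <- which(m$atoms$element %in% c("N", "O"))
  contribs <- data.frame(atom = integer(), element = character(),
                         contribution = numeric(), stringsAsFactors = FALSE)
  total <- 0
  for (i in polar) {
    b <- m$bonds[m$bonds$a1 == i | m$bonds$a2 == i, , drop = FALSE]
    key <- list(element = m$atoms$element[i],
                n_h = m$atoms$n_h[i],
                n_single = sum(b$order == 1L),
                n_double = sum(b$order == 2L),
                n_triple = sum(b$order == 3L),
                in_ring3 = ring3[i])
    hit <- tab$element == key$element & tab$n_h == key$n_h &
      tab$n_single == key$n_single & tab$n_double == key$n_double &
      tab$n_triple == key$n_triple & tab$in_ring3 == key$in_ring3
    if (m$atoms$charge[i] != 0L || !any(hit)) {
      warning("no tabulated polar-surface contribution for ",
              key$element, " atom ", i, " (", key$n_h, "H, ",
              key$n_single, "s/", key$n_double, "d/", key$n_triple, "t",
              if (m$atoms$charge[i] != 0L) ", charged", "); counted as zero",
              call. = FALSE)
      val <- 0
    } else {
      val <- tab$contribution[hit][1]
    }
    total <- total + val
    contribs <- rbind(contribs, data.frame(atom = i, element = key$element,
                                           contribution = val,
                                           stringsAsFactors = FALSE))
  }
  if (breakdown) list(tpsa = total, contributions = contribs) else total
}
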