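# Synthetic-data generator: nitrosourea analog enumeration on the fixed
# O=C(NHR)N(N=O)CH2CH2Cl core, and descriptor tables with the statistical
# structure of the reference agent set.

# SMILES prefix of the nitrosourea core; the R group is spliced after the
# amide nitrogen (C-linked substituents only, as in every reference agent).
nitrosourea_core_prefix <- function() "ClCCN(N=O)C(=O)N"

#' Substituent library for analog enumeration
#'
#' R-group SMILES fragments with category tags spanning the substituent
#' chemistry seen across the reference agents: cycloalkyl and other carbon
#' rings, aliphatic and alkenyl chains, halogenated chains, hydroxyalkyl
#' groups and sulfur-bearing groups. Each fragment carries exactly one
#' attachment point, written as a leading `*`.
#'
#' @return Data frame with columns `name`, `smiles`, `category`.
#' @export
substituent_library <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name smiles category
cyclohexyl *C1CCCCC1 cycloalkyl
cyclopentyl *C1CCCC1 cycloalkyl
cyclobutyl *C1CCC1 cycloalkyl
cyclopropyl *C1CC1 cycloalkyl
ethyl *CC alkyl
propyl *CCC alkyl
isopropyl *C(C)C alkyl
butyl *CCCC alkyl
isobutyl *CC(C)C alkyl
allyl *CC=C alkenyl
but-3-enyl *CCC=C alkenyl
2-methylallyl *CC(=C)C alkenyl
2-chloroethyl *CCCl halogenated
3-bromopropyl *CCCBr halogenated
4-chlorocyclohexyl *C1CCC(Cl)CC1 halogenated
2-hydroxypropyl *CC(O)C hydroxyalkyl
3-hydroxypropyl *CCCO hydroxyalkyl
oxan-4-yl *C1CCOCC1 ring
cyclohexylmethyl *CC1CCCCC1 ring
2-methylsulfanylethyl *CCSC thio
thiolan-3-yl *C1CCSC1 thio
")
}

validate_fragment <- function(smiles) {
  n_attach <- lengths(regmatches(smiles, gregexpr("*", smiles, fixed = TRUE)))
  if (n_attach == 0L)
    stop_input("fragment '", smiles, "' has no attachment point ('*')")
  if (n_attach > 1L)
    stop_input("fragment '", smiles, "' has ", n_attach, " attachment points; exactly one required")
  if (!startsWith(smiles, "*"))
    stop_input("fragment '", smiles, "' must start with its attachment point")
  invisible(smiles)
}

#' Enumerate nitrosourea analogs from a substituent library
#'
#' Splices R groups onto the fixed alkylating core
#' `O=C(NHR)N(N=O)CH2CH2Cl`; the cyclohexyl fragment yields lomustine.
#' Deterministic for a given seed.
#'
#' @param lib Data frame as from [substituent_library()].
#' @param n Number of analogs to draw.
#' @param seed RNG seed.
#' @param replace Sample fragments with replacement; without it `n` must not
#'   exceed the number of distinct fragments.
#' @return List of [parse_smiles()] molecules, identified as
#'   `"<fragment name> analog"`.
#' @examples
#' mols <- enumerate_analogs(substituent_library(), n = 3, seed = 1)
#' @export
enumerate_analogs <- function(lib, n, seed, replace = FALSE) {
  if (missing(seed)) stop_input("enumerate_analogs: a seed is required")
  if (!all(c("name", "smiles") %in% names(lib)))
    stop_input("substituent library needs 'name' and 'smiles' columns")
  for (s in lib$smiles) validate_fragment(s)
  if (!replace && n > nrow(lib))
    stop_input("n exceeds the ", nrow(lib),
               " distinct fragments; use replace = TRUE to sample with replacement")
  set.seed(seed)
  idx <- sample.int(nrow(lib), n, replace = replace)
  lapply(seq_along(idx), function(k) {
    i <- idx[k]
    smi <- paste0(nitrosourea_core_prefix(), substring(lib$smiles[i], 2))
    parse_smiles(smi, identifier = paste0(lib$name[i], " analog"))
  })
}

#' Simulate a descriptor table with the reference set's structure
#'
#' Emulates the statistical structure of the reference agent table: Log P
#' normal (truncated to bracket the observed 1.537-3.924 range with margin),
#' near-constant PSA at 61.77 with a rare hydroxylated variant at 82.0 (which
#' also carries one extra O/N and one extra donor hydrogen, mirroring agent
#' 12's signature), integer atom and rotatable-bond counts uniform over the
#' observed ranges, and formula weight regenerated from the linear
#' formula-weight relation plus Gaussian noise, clamped to `fw_range`.
#' Molecular volume follows its near-linear relation to atom count.
#' Reproducible bit-for-bit for a fixed seed and parameter set.
#'
#' @param n_compounds Number of records (at least 1).
#' @param seed RNG seed (required).
#' @param log_p_mean,log_p_sd Log P distribution (defaults: the reference
#'   set's mean 2.524 and sample SD 0.5337); `log_p_sd` must be positive.
#' @param log_p_range Truncation bounds for Log P.
#' @param hydroxylated_fraction Probability that a record is the hydroxylated
#'   variant (default 1/18, the reference set's rate).
#' @param n_hydroxylated Exact number of hydroxylated records; overrides the
#'   fraction (e.g. 1 to mirror the reference set's single agent 12).
#' @param fw_range Clamp range for formula weight (daltons).
#' @param fw_noise_sd SD of the Gaussian noise on the formula-weight relation
#'   (default 16, the residual scale of the relation on the reference set).
#' @return A `descriptor_table` with provenance `"synthetic"`.
#' @examples
#' simulate_descriptor_table(18, seed = 42, n_hydroxylated = 1)
#' @export
simulate_descriptor_table <- function(n_compounds, seed,
                                      log_p_mean = 2.524, log_p_sd = 0.5337,
                                      log_p_range = c(1.0, 4.5),
                                      hydroxylated_fraction = 1 / 18,
                                      n_hydroxylated = NULL,
                                      fw_range = c(190, 315),
                                      fw_noise_sd = 16) {
  if (missing(seed)) stop_input("simulate_descriptor_table: a seed is required")
  if (n_compounds < 1L) stop_input("n_compounds must be at least 1")
  if (log_p_sd <= 0) stop_input("log_p_sd must be positive")
  if (hydroxylated_fraction < 0 || hydroxylated_fraction > 1)
    stop_input("hydroxylated_fraction must be in [0, 1]")
  set.seed(seed)
  n <- n_compounds
  # inverse-CDF truncated normal: deterministic given the seed
  plo <- stats::pnorm(log_p_range[1], log_p_mean, log_p_sd)
  phi <- stats::pnorm(log_p_range[2], log_p_mean, log_p_sd)
  log_p <- stats::qnorm(stats::runif(n, plo, phi), log_p_mean, log_p_sd)
  hydroxy <- if (!is.null(n_hydroxylated)) {
    if (n_hydroxylated > n) stop_input("n_hydroxylated exceeds n_compounds")
    h <- logical(n)
    h[sample.int(n, n_hydroxylated)] <- TRUE
    h
  } else stats::runif(n) < hydroxylated_fraction
  psa <- ifelse(hydroxy, 82.0, 61.77)
  n_on <- ifelse(hydroxy, 6L, 5L)
  n_ohnh <- ifelse(hydroxy, 2L, 1L)
  n_atoms <- sample(12:17, n, replace = TRUE)
  n_rot <- sample(4:8, n, replace = TRUE)
  fw <- -24.859 + 0.9578 * log_p - 0.04598 * psa + 19.236 * n_atoms -
    3.947 * n_rot + stats::rnorm(n, 0, fw_noise_sd)
  fw <- pmin(pmax(fw, fw_range[1]), fw_range[2])
  volume <- -19.637 + 15.311 * n_atoms + stats::rnorm(n, 0, 5.4)
  df <- data.frame(agent_id = paste0("S", seq_len(n)),
                   log_p = log_p, psa = psa, n_atoms = as.integer(n_atoms),
                   fw = fw, n_on = as.integer(n_on),
                   n_ohnh = as.integer(n_ohnh),
                   n_rot = as.integer(n_rot), volume = volume,
                   stringsAsFactors = FALSE)
  df$n_ro5_violations <- rule_of_five_violations(df)
  descriptor_table(df[, c("agent_id", "log_p", "psa", "n_atoms", "fw", "n_on",
                          "n_ohnh", "n_ro5_violations", "n_rot", "volume")],
                   provenance = "synthetic")
}

#' Construct a screening fixture with a known pass count
#'
#' Builds a table in which exactly `n_pass` records satisfy all three screens
#' (CNS-A, CNS-B, zero Rule-of-5 violations) and the remaining records each
#' violate at least one criterion (failure modes cycle deterministically:
#' oversized formula weight, excessive Log P, excessive polar surface area,
#' too many H-bond donors). Mirrors a library search in which few generated
#' structures meet the CNS criteria.
#'
#' @param n_total Total number of records.
#' @param n_pass Number of records passing every screen (`<= n_total`).
#' @param seed RNG seed (required).
#' @return A `descriptor_table` with provenance `"synthetic"`.
#' @examples
#' fx <- screening_fixture(200, 17, seed = 7)
#' screen_library(fx)$overall_fraction  # 0.085
#' @export
screening_fixture <- function(n_total, n_pass, seed) {
  if (missing(seed)) stop_input("screening_fixture: a seed is required")
  if (n_pass > n_total) stop_input("n_pass cannot exceed n_total")
  if (n_total < 1L) stop_input("n_total must be at least 1")
  df <- as.data.frame(simulate_descriptor_table(n_total, seed = seed))
  n_fail <- n_total - n_pass
  if (n_fail > 0L) {
    fail_idx <- seq(n_pass + 1L, n_total)
    mode <- (seq_along(fail_idx) - 1L) %% 4L
    for (k in seq_along(fail_idx)) {
      i <- fail_idx[k]
      if (mode[k] == 0L) {
        df$fw[i] <- stats::runif(1, 465, 620)            # fails both FW cutoffs
      } else if (mode[k] == 1L) {
        df$log_p[i] <- stats::runif(1, 5.3, 6.8)         # fails Log P <= 5
      } else if (mode[k] == 2L) {
        df$psa[i] <- stats::runif(1, 95, 140)            # fails PSA <= 90
      } else {
        df$n_ohnh[i] <- sample(4:6, 1)                   # fails donors <= 3
        df$n_on[i] <- df$n_ohnh[i] + 4L
      }
    }
  }
  df$n_ro5_violations <- rule_of_five_violations(df)
  descriptor_table(df, provenance = "synthetic")
}
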