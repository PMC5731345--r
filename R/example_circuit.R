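#' Synthetic example circuit annotation
#'
#' Builds a synthetic three-input, one-output combinatorial logic circuit of
#' 46 genetic parts: three sensor output promoters feed five NOR/NOT gates
#' (repressor transcription units insulated by ribozymes), ending in a
#' fluorescent-reporter output unit; assembly scars separate the units. The
#' layout emulates the architecture of published RNA-seq-characterized
#' circuits but the coordinates and part sizes are synthetic, intended for
#' examples, tests and simulation.
#'
#' @return A [circuit_annotation()] on reference `"circuit_synthetic"`.
#' @export
example_circuit_annotation <- function() {
  rows <- list()
  pos <- 101L
  add <- function(name, type, len, cut_offset = NA, tss_at_end = FALSE) {
    start <- pos
    end <- pos + len - 1L
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, part_type = type, start = start, end = end, strand = "+",
      cut_site = if (is.na(cut_offset)) NA_real_ else start + cut_offset,
      tss = if (tss_at_end) end else NA_real_,
      stringsAsFactors = FALSE)
    pos <<- end + 1L
  }
  scar_i <- 0L
  scar <- function() {
    scar_i <<- scar_i + 1L
    add(sprintf("scar%02d", scar_i), "scar", 20L)
  }
  tu <- function(promoters, ribozyme, gene, gene_len, terminator) {
    for (pr in promoters) add(pr, "promoter", 35L, tss_at_end = TRUE)
    add(ribozyme, "ribozyme", 75L, cut_offset = 40L)
    add(paste0("rbs_", gene), "rbs", 20L)
    add(gene, "cds", gene_len)
    add(terminator, "terminator", 60L)
  }
  scar()
  tu(c("P_Tac", "P_Tet1"), "RiboJ53", "AmtR", 700L, "ECK120029600")
  scar()
  tu(c("P_BAD1", "P_Tet2"), "RiboJ10", "LitR", 650L, "L3S2P55")
  scar()
  tu("P_BAD2", "RiboJ64", "BM3R1", 450L, "L3S2P11")
  scar()
  tu(c("P_BM3R1", "P_AmtR"), "RiboJ54", "SrpR", 700L, "ECK120033737")
  scar()
  tu(c("P_SrpR", "P_LitR"), "RiboJ", "PhlF", 620L, "L3S2P24")
  scar()
  tu("P_PhlF", "BydvJ", "yfp", 720L, "L3S2P21")
  for (i in 1:6) scar()
  parts <- do.call(rbind, rows)
  circuit_annotation(parts, "circuit_synthetic", pos + 300L)
}

#' Ground truth for the example circuit under the eight input states
#'
#' Per-state promoter activities (au/s) implementing the logic of the
#' example circuit: each sensor promoter is on when its inducer is present;
#' each gate's output promoter activity follows its repressor state.
#' Activities are chosen in the au/s range reported for circuits of this
#' kind. States are labelled by inducer presence, e.g. `"-/+/-"` for
#' IPTG absent, aTc present, arabinose absent.
#'
#' @param gamma mRNA degradation rate (s^-1).
#' @param sigma Lognormal noise sd on activities (default 0).
#' @return A [ground_truth()] covering all eight inducer combinations.
#' @export
example_circuit_truth <- function(gamma = 0.0067, sigma = 0) {
  sensors <- list(  # off/on activities per sensor output promoter
    P_Tac = c(0.1, 9), P_Tet1 = c(0.1, 16), P_Tet2 = c(0.8, 50),
    P_BAD1 = c(0.8, 40), P_BAD2 = c(0.1, 13))
  gates <- list(    # gate output promoters: c(dJ_min, dJ_max, K, n)
    P_AmtR = c(0.5, 30, 2, 1.6), P_LitR = c(0.4, 25, 3, 1.8),
    P_BM3R1 = c(0.6, 28, 2.5, 1.7), P_SrpR = c(0.5, 35, 3, 1.9),
    P_PhlF = c(0.8, 45, 4, 1.7))
  hill <- function(g, jin) {
    g[1] + (g[2] - g[1]) * g[3]^g[4] / (g[3]^g[4] + jin^g[4])
  }
  combos <- expand.grid(iptg = c(FALSE, TRUE), atc = c(FALSE, TRUE),
                        ara = c(FALSE, TRUE))
  acts <- list()
  for (i in seq_len(nrow(combos))) {
    s <- combos[i, ]
    a <- c(P_Tac = sensors$P_Tac[1 + s$iptg],
           P_Tet1 = sensors$P_Tet1[1 + s$atc],
           P_Tet2 = sensors$P_Tet2[1 + s$atc],
           P_BAD1 = sensors$P_BAD1[1 + s$ara],
           P_BAD2 = sensors$P_BAD2[1 + s$ara])
    a["P_AmtR"] <- hill(gates$P_AmtR, a["P_Tac"] + a["P_Tet1"])
    a["P_LitR"] <- hill(gates$P_LitR, a["P_BAD1"] + a["P_Tet2"])
    a["P_BM3R1"] <- hill(gates$P_BM3R1, a["P_BAD2"])
    a["P_SrpR"] <- hill(gates$P_SrpR, a["P_BM3R1"] + a["P_AmtR"])
    a["P_PhlF"] <- hill(gates$P_PhlF, a["P_SrpR"] + a["P_LitR"])
    state <- paste(ifelse(unlist(s), "+", "-"), collapse = "/")
    acts[[state]] <- a
  }
  ground_truth(
    promoter_activities = acts,
    terminator_Ts = c(ECK120029600 = 380, L3S2P55 = 24, L3S2P11 = 110,
                      ECK120033737 = 800, L3S2P24 = 290, L3S2P21 = 190),
    ribozyme_pc = c(RiboJ53 = 0.95, RiboJ10 = 0.9, RiboJ64 = 0.92,
                    RiboJ54 = 0.94, RiboJ = 0.93, BydvJ = 0.96),
    gamma = gamma, sigma = sigma)
}
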