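#' Nearest-neighbor DNA folding parameters (37 degC, 1 M NaCl)
#'
#' Unified DNA nearest-neighbor Watson-Crick stacking free energies
#' (kcal/mol at 37 degC, 1 M monovalent salt) together with tabulated
#' destabilizing loop penalties for hairpin, bulge and internal loops.
#' Loop penalties between tabulated anchor sizes are linearly
#' interpolated; beyond 30 nt they are extrapolated as
#' `dG(n) = dG(30) + 1.75 * R * T * log(n/30)` (Jacobson-Stockmayer).
#' The table is deliberately self-contained: every folding test in this
#' package scores structures by hand from the same table, so the
#' contract is internal consistency, not bit-compatibility with any
#' external folder.
#'
#' @return list with elements `stack` (4x4 matrix, rows/cols A,C,G,T:
#'   entry \[x,y\] is the free energy of the dinucleotide step 5'-xy-3'
#'   paired to its Watson-Crick complement), `hairpin`, `bulge`,
#'   `internal` (penalty vectors indexed by loop size 1..30, kcal/mol),
#'   `lxc` (log-extrapolation coefficient), `asym`/`asym_max` (internal
#'   loop asymmetry penalty per unpaired-base difference and its cap),
#'   `wobble_stack` (flat stack value used for G.T-containing steps when
#'   wobble pairing is enabled), `min_hairpin` (3), `max_loop` (30).
#' @export
dna_nn_params <- function() {
  b <- c("A", "C", "G", "T")
  stack <- matrix(c(
    # columns: second base A, C, G, T; rows: first base
    -1.00, -1.44, -1.28, -0.88,   # AA, AC, AG, AT
    -1.45, -1.84, -2.17, -1.28,   # CA, CC, CG, CT
    -1.30, -2.24, -1.84, -1.44,   # GA, GC, GG, GT
    -0.58, -1.30, -1.45, -1.00),  # TA, TC, TG, TT
    nrow = 4, byrow = TRUE, dimnames = list(b, b))
  interp <- function(sizes, vals) {
    approx(sizes, vals, xout = 1:30, rule = 2)$y
  }
  hairpin <- interp(c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
                    c(3.5, 3.5, 3.3, 4.0, 4.3, 4.3, 4.5, 4.6, 5.0, 5.1,
                      5.3, 5.5, 5.7, 6.1, 6.3))
  hairpin[1:2] <- Inf   # loops below 3 nt are sterically forbidden
  bulge <- interp(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
                  c(4.0, 2.9, 3.1, 3.2, 3.3, 3.5, 3.7, 3.9, 4.0, 4.1,
                    4.3, 4.5, 4.7, 4.9, 5.0, 5.3, 5.5))
  internal <- interp(c(2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
                     c(4.1, 3.2, 3.6, 4.0, 4.4, 4.6, 4.8, 4.9, 4.9, 5.2,
                       5.4, 5.6, 5.8, 5.9, 6.3, 6.6))
  list(stack = stack, hairpin = hairpin, bulge = bulge, internal = internal,
       lxc = 1.75 * 0.0019872 * 310.15,
       asym = 0.3, asym_max = 3.0, wobble_stack = -0.3,
       min_hairpin = 3L, max_loop = 30L,
       temperature_c = 37, na_molar = 1.0, mg_molar = 0.0)
}

#' @importFrom stats approx
NULL
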