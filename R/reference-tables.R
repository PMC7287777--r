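#' Reference fatty-acyl compositions
#'
#' `plasma_fa_reference()`: relative fatty-acyl composition (%) of the
#' four most abundant phospholipid classes of healthy human plasma (PI,
#' PE, PC, LPC), with replicate standard deviations, as estimated from
#' negative-mode AIF carboxylate signals. `bovine_pi_reference()`: the
#' acyl-chain distribution of a commercial bovine-liver PI extract
#' estimated by the same AIF readout. These tables drive
#' [plasma_like_config()] and serve as the default chain universe for
#' [fa_profile()].
#'
#' @return A tibble with `carbons`, `double_bonds`, `chain` label, and
#'   per-class percentage columns (NA where the chain was not observed).
#' @export
plasma_fa_reference <- function() {
  x <- tibble::tribble(
    ~carbons, ~double_bonds,   ~pi, ~pi_sd,   ~pe, ~pe_sd,   ~pc, ~pc_sd,  ~lpc, ~lpc_sd,
    14L, 0L,      NA,   NA,  0.14, 0.01,  1.65, 0.07,  0.27, 0.01,
    16L, 0L,    11.7,  1.2,  4.79, 0.06, 19.43, 0.16, 40.0,  0.3,
    16L, 1L,      NA,   NA,  0.79, 0.08,  1.66, 0.01,  0.71, 0.11,
    17L, 0L,      NA,   NA,  0.18, 0.01,  0.44, 0.01,  1.21, 0.01,
    17L, 1L,      NA,   NA,  0.33, 0.12,  0.31, 0.01,  0.21, 0.02,
    18L, 0L,    29.2,  1.7,  4.85, 0.04,  6.07, 0.07, 26.51, 0.12,
    18L, 1L,     9.8,  0.7,  14.7,  0.4, 14.55, 0.05, 16.55, 0.08,
    18L, 2L,    6.64, 0.19,  21.7,  0.7,  29.2,  0.2,  12.1,  0.2,
    18L, 3L,    0.11, 0.01,  0.36, 0.01,  0.46, 0.01,  0.11, 0.01,
    20L, 1L,      NA,   NA,  0.20, 0.01,  0.11, 0.01,  0.22, 0.01,
    20L, 2L,    0.22, 0.03,  0.15, 0.01,  0.29, 0.01,  0.21, 0.01,
    20L, 3L,    4.16, 0.10,  4.30, 0.03,  4.56, 0.05,  1.14, 0.07,
    20L, 4L,    34.4,  0.7,  33.9,  0.3,  15.8,  0.2,  0.77, 0.04,
    20L, 5L,      NA,   NA,  1.17, 0.02,  0.58, 0.01,    NA,   NA,
    22L, 3L,      NA,   NA,  0.06, 0.01,  0.01, 0.01,    NA,   NA,
    22L, 4L,    0.34, 0.05,  1.89, 0.02,  0.48, 0.02,    NA,   NA,
    22L, 5L,    0.99, 0.03,  4.00, 0.08,  1.25, 0.01,    NA,   NA,
    22L, 6L,    2.44, 0.12,  6.53, 0.14,  3.12, 0.04,    NA,   NA
  )
  mutate(x,
         chain = paste0("FA C", .data$carbons, ":", .data$double_bonds),
         mz = carboxylate_mz(.data$carbons, .data$double_bonds),
         .before = 1)
}

#' @rdname plasma_fa_reference
#' @export
bovine_pi_reference <- function() {
  x <- tibble::tribble(
    ~carbons, ~double_bonds, ~estimated_pct,
    16L, 0L,  6.3,
    16L, 1L,  0.5,
    17L, 0L,  1.5,
    18L, 0L, 37.6,
    18L, 1L, 12.0,
    18L, 2L, 11.6,
    18L, 3L,  0.7,
    20L, 2L,  1.6,
    20L, 3L, 10.6,
    20L, 4L, 17.0,
    20L, 5L,  0.7,
    22L, 4L,  1.6,
    22L, 5L,  1.2
  )
  mutate(x,
         chain = paste0("FA C", .data$carbons, ":", .data$double_bonds),
         mz = carboxylate_mz(.data$carbons, .data$double_bonds),
         .before = 1)
}
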