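# Shared fixtures: the reference parameter set used throughout the
# validation experiments (CMRO2 = 2 umol cm^-3 min^-1, Rt = 80 um,
# Pves = 60 mmHg, Rves = 10 um) and small synthetic grids.

ref_constants <- tissue_constants()

ref_krogh <- function(cmro2 = 2) {
  krogh_params(cmro2 = cmro2, p_ves = 60, r_ves = 10, r_t = 80,
               constants = ref_constants)
}

# radially symmetric Krogh-with-plateau pO2 sampled on an n x n lattice
symmetric_grid <- function(p = ref_krogh(), n = 61, fov = 300) {
  g <- square_grid(n, fov)
  r <- sqrt(g$x_um^2 + g$y_um^2)
  po2 <- ifelse(r < p$r_ves, p$p_ves,
         ifelse(r <= p$r_t, krogh_po2(pmin(pmax(r, p$r_ves), p$r_t), p),
                krogh_po2(p$r_t, p)))
  as_po2_grid(tibble::tibble(x_um = g$x_um, y_um = g$y_um, po2_mmhg = po2),
              center = c(0, 0), r_ves_um = p$r_ves)
}

# the generating piecewise radial function of symmetric_grid()
krogh_plateau_fun <- function(r, p = ref_krogh()) {
  ifelse(r < p$r_ves, p$p_ves,
  ifelse(r <= p$r_t, krogh_po2(pmin(pmax(r, p$r_ves), p$r_t), p),
         krogh_po2(p$r_t, p)))
}

# cmro2/(4 D alpha) in mmHg/um^2, independent re-derivation for oracles
oracle_quarter_coef <- function(cmro2, cst = ref_constants) {
  (cmro2 / 60) / (4 * cst$d_cm2_per_s * cst$alpha_uM_per_mmHg * 1e-3) * 1e-8
}
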