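# shared fixtures built in code

compounds_tbl <- psychotropic_compounds()
ami_row <- dplyr::filter(compounds_tbl, name == "AMI")
cur_row <- dplyr::filter(compounds_tbl, name == "CUR")

# printed one-decimal mean logP per compound
printed_logp_av <- c(AMI = 5.0, COU = 4.7, CUR = 2.9, NOR = 4.5, PRO = 3.0)

# a tiny fast simulator config for structural tests
fast_config <- function(seed = 1L, ...) {
  sim_config(ami_row, "No. 1", flow_rate_ml_min = 1, c0_solvent_mM = 79.7,
             antisolvent_ml = 200, naoh_mM = 1, seed = seed, ...)
}

# independent least-squares oracle: normal equations evaluated directly
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - sy / n)^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}
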