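# Independent oracles and tiny fixture builders used across the suite.

# Exhaustive permutation oracle for the two-sided Mann-Whitney p-value:
# every assignment of group labels to the pooled values, symmetric tail sum.
mw_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  m <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  big_m <- m * length(b)
  combos <- utils::combn(n, m)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  u_lo <- min(u_obs, big_m - u_obs)
  u_hi <- max(u_obs, big_m - u_obs)
  min(1, (sum(us <= u_lo) + sum(us >= u_hi)) / ncol(combos))
}

# Plain-arithmetic scorers, written independently of the point-table engine.
oracle_faced <- function(fev1, age, pa, lobes, mmrc) {
  (fev1 < 50) * 2 + (age > 70) * 2 + pa * 1 + (lobes > 2) * 1 + (mmrc >= 3) * 1
}
oracle_efaced <- function(fev1, age, pa, lobes, mmrc, hosp) {
  oracle_faced(fev1, age, pa, lobes, mmrc) + (hosp >= 1) * 2
}
oracle_bsi <- function(age, bmi, fev1, hosp, exac, mmrc, pa, other,
                       lobes, cystic) {
  age_pts <- ifelse(age < 50, 0, ifelse(age < 70, 2, ifelse(age < 80, 4, 6)))
  fev1_pts <- ifelse(fev1 > 80, 0, ifelse(fev1 >= 50, 1,
    ifelse(fev1 >= 30, 2, 3)
  ))
  mmrc_pts <- ifelse(mmrc >= 4, 3, ifelse(mmrc >= 3, 2, 0))
  age_pts + (bmi < 18.5) * 2 + fev1_pts + (hosp >= 1) * 5 + (exac >= 3) * 2 +
    mmrc_pts + pa * 3 + other * 1 + (lobes >= 3 | cystic) * 1
}

oracle_category <- function(total, scale) {
  b <- switch(scale,
    FACED = c(3, 5),
    EFACED = c(4, 7),
    BSI = c(5, 9)
  )
  ifelse(total >= b[2], "severe", ifelse(total >= b[1], "moderate", "mild"))
}

# A tiny hand-built cohort exercising every scoring band.
tiny_cohort <- function() {
  tibble::tibble(
    patient_id = sprintf("T%02d", 1:6),
    age = c(40, 75, 85, 60, 72, 55),
    bmi = c(17, 25, 30, 22, 19, 24),
    fev1_pct = c(90, 45, 25, 60, 78, 82),
    fvc_pct = c(95, 60, 40, 75, 85, 90),
    fev1_fvc = c(80, 60, 50, 70, 75, 78),
    dlco_pct = c(90, 60, 40, 75, 80, 85),
    dyspnea_mmrc = c(0L, 3L, 4L, 1L, 2L, 0L),
    radiological_lobes = c(1L, 4L, 6L, 2L, 3L, 1L),
    exacerbations_prior_year = c(0L, 3L, 5L, 1L, 2L, 0L),
    hospitalizations_prior_year = c(0L, 1L, 2L, 0L, 1L, 0L),
    charlson = c(0L, 2L, 4L, 1L, 2L, 1L),
    pa_colonization = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    other_colonization = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    cystic_bronchiectasis = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    copd = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    asthma = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    smoking_status = c("never", "ex", "current", "never", "ex", "never"),
    pack_years = c(0, 30, 45, 0, 20, 0),
    neutrophils = c(2500, 7200, 9100, 3900, 5400, 3100),
    lymphocytes = c(2000, 1800, 1500, 2200, 1900, 2100),
    eosinophils = c(200, 150, 100, 250, 180, 220),
    leukocytes = c(5200, 9800, 11400, 6900, 8100, 5900),
    platelets = c(230000, 280000, 310000, 240000, 260000, 235000),
    crp = c(0.5, 6.2, 11.0, 1.2, 3.8, 0.9),
    esr = c(8, 25, 40, 12, 18, 10),
    fibrinogen = c(350, 520, 600, 380, 450, 360),
    total_protein = c(7.2, 6.8, 6.5, 7.1, 6.9, 7.0),
    albumin = c(4.4, 4.0, 3.8, 4.3, 4.1, 4.2)
  )
}

# A fortified effect configuration: the "strong plant" used by recovery
# simulations (FACED/EFACED component inputs shifted hard at the threshold).
strong_effects <- function() {
  list(
    fev1_pct = -25, age = 8,
    pa_colonization = c(0.215, 0.50),
    dyspnea_mmrc = c(0.15, 0.20, 0.25, 0.20, 0.20),
    hospitalizations_prior_year = 1.2
  )
}
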