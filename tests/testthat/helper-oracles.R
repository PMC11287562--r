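# Independent brute-force oracles and small fixture builders.

# O(n^2) weighted Mann-Whitney AUC, ties counted one half.
auc_brute <- function(pred, y, w = rep(1, length(pred))) {
  ci <- which(y > 0)
  co <- which(y == 0)
  num <- 0
  den <- 0
  for (i in ci) {
    for (j in co) {
      pw <- w[i] * w[j]
      num <- num + pw * ((pred[i] > pred[j]) + 0.5 * (pred[i] == pred[j]))
      den <- den + pw
    }
  }
  num / den
}

# O(n^2) Harrell's C: pair comparable iff the strictly earlier time is an
# event; concordant iff that member has the higher prediction; prediction
# ties count one half; pair weight is the product of member weights.
cindex_brute <- function(pred, time, event, w = rep(1, length(pred))) {
  num <- 0
  den <- 0
  n <- length(pred)
  for (i in seq_len(n)) {
    if (!event[i]) next
    for (j in seq_len(n)) {
      if (i == j || !(time[i] < time[j])) next
      pw <- w[i] * w[j]
      den <- den + pw
      num <- num + pw * ((pred[i] > pred[j]) + 0.5 * (pred[i] == pred[j]))
    }
  }
  num / den
}

# Monte-Carlo competing-risk absolute risk for fixed per-band rates,
# by direct inverse-transform sampling (independent of the package's
# integration and drawing code).
mc_risk <- function(lam_band, mu_band, breaks, start, end, nrep, seed) {
  set.seed(seed)
  draw <- function(rates) {
    H <- -log(runif(nrep))
    t <- rep(Inf, nrep)
    acc <- 0
    for (k in seq_along(rates)) {
      lo <- max(start, breaks[k])
      hi <- breaks[k + 1L]
      if (hi <= start) next
      nxt <- acc + rates[k] * (hi - lo)
      hit <- is.infinite(t) & H <= nxt & rates[k] > 0
      t[hit] <- lo + (H[hit] - acc) / rates[k]
      acc <- nxt
    }
    t
  }
  tb <- draw(lam_band)
  td <- draw(mu_band)
  hit <- tb < end & tb < td
  p <- mean(hit)
  list(p = p, se = sqrt(p * (1 - p) / nrep))
}

# Per-band individual hazard computed by plain arithmetic (multiplicative
# model written out), for feeding the MC oracle.
oracle_lambda <- function(model, gene, prs_z = 0, qrf = character(),
                          fh = 0) {
  lp <- model$log_rr_gene[[gene]] + prs_z * model$log_rr_prs
  for (f in names(qrf)) lp <- lp + model$log_rr_qrf[[f]][[qrf[[f]]]]
  lp <- lp + fh * model$log_rr_fh
  model$bc_incidence * exp(lp)
}

# Minimal hand-built cohort rows for the preparation tests.
make_record <- function(id = "W1", baseline_age = 40, bc_age = NA,
                        bc_is_dcis = FALSE, death_age = NA,
                        mastectomy_age = NA, rrso_age = NA,
                        last_followup_age = 49, country = "UK",
                        gene = "BRCA1", prs_z = 0, fh_score = 0,
                        qrf_parity = "parous", qrf_mht = "never",
                        qrf_bmi = "normal") {
  data.frame(id = id, country = country, gene = gene,
             baseline_age = baseline_age, prs_raw = NA_real_, prs_z = prs_z,
             qrf_parity = qrf_parity, qrf_mht = qrf_mht, qrf_bmi = qrf_bmi,
             fh_score = fh_score, bc_age = as.numeric(bc_age),
             bc_is_dcis = bc_is_dcis, death_age = as.numeric(death_age),
             mastectomy_age = as.numeric(mastectomy_age),
             rrso_age = as.numeric(rrso_age),
             last_followup_age = last_followup_age, included = TRUE,
             stringsAsFactors = FALSE)
}

# A small two-band model with flat rates, handy for closed-form checks.
flat_model <- function(lambda = 0.02, mu = 0, lo = 20, hi = 80) {
  hazard_model(c(lo, (lo + hi) / 2, hi), bc_incidence = lambda,
               mortality = mu,
               log_rr_gene = list(BRCA1 = 0, BRCA2 = 0), log_rr_prs = 0)
}
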