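# Small hand-built follow-up record sets used across estimation tests.

record_row <- function(patient_id, visit_index, state = "L1",
                       sbp = 150, dbp = 95, arm = "usual",
                       scores = rep(70, 8)) {
  data.frame(patient_id = patient_id, arm = arm, visit_index = visit_index,
             sbp = sbp, dbp = dbp, state = state,
             pf = scores[1], rp = scores[2], bp = scores[3], gh = scores[4],
             vt = scores[5], sf = scores[6], re = scores[7], mh = scores[8],
             stringsAsFactors = FALSE)
}

# n patients with a fixed baseline -> final transition, optional middle visits
make_cohort <- function(n, from = "L1", to = "L1", final_visit = 12L,
                        arm = "usual") {
  do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(record_row(sprintf("p%03d", i), 0L, state = from, arm = arm),
          record_row(sprintf("p%03d", i), final_visit, state = to, arm = arm))
  }))
}

# SF-36 score set where every dimension has the same value
flat_scores <- function(value) {
  stats::setNames(rep(value, 8), c("PF", "RP", "BP", "GH", "VT", "SF",
                                   "RE", "MH"))
}
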