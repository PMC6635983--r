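# Hand-built participant tables for unit tests (no file fixtures needed).

# one record with overridable fields; defaults are a valid responder
make_record <- function(id = "P1", age = 30L,
                        nf = 0L, cbr = 0L, smf = 0L, ap = 0L, ic = 0L,
                        baseline_pwac = 40, baseline_audit = 12L,
                        followup_pwac = 20, followup_audit = 10L,
                        phase = "original", ...) {
  responded <- !is.na(followup_pwac)
  data.frame(id = id, age = age,
             mod_nf = nf, mod_cbr = cbr, mod_smf = smf, mod_ap = ap,
             mod_ic = ic,
             baseline_pwac = baseline_pwac, baseline_audit = baseline_audit,
             followup_pwac = followup_pwac, followup_audit = followup_audit,
             responded = responded, phase = phase,
             stringsAsFactors = FALSE, ...)
}

make_records <- function(...) do.call(rbind, list(...))

# n records per phase with the first `responders` of each responding;
# allocation alternates so both levels of every module are present
make_phase_records <- function(n_original, resp_original,
                               n_extended = 0L, resp_extended = 0L) {
  build <- function(n, r, phase, offset) {
    if (n == 0L) return(NULL)
    i <- seq_len(n)
    responded <- i <= r
    data.frame(id = sprintf("%s%06d", substr(phase, 1, 1), i + offset),
               age = 30L,
               mod_nf = i %% 2L, mod_cbr = (i %/% 2L) %% 2L,
               mod_smf = (i %/% 4L) %% 2L, mod_ap = (i %/% 8L) %% 2L,
               mod_ic = (i %/% 16L) %% 2L,
               baseline_pwac = 40, baseline_audit = 12L,
               followup_pwac = ifelse(responded, 30, NA_real_),
               followup_audit = ifelse(responded, 11L, NA_integer_),
               responded = responded, phase = phase,
               stringsAsFactors = FALSE)
  }
  rbind(build(n_original, resp_original, "original", 0L),
        build(n_extended, resp_extended, "extended", n_original))
}
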