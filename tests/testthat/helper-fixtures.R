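## Shared fixtures: small grids and toy peak tables built in code.

toyAcq <- function(n = 256L, nucleus = "P31") {
  AcquisitionParams(nucleus, n_points = n)
}

## Well-separated three-line toy table on the 31P grid.
toyTable <- function(shifts = c(-5, 0, 5), amps = c(1, 2, 1.5), lw = 20,
                     names = c("A", "B", "C"), nucleus = "P31") {
  PeakTable(data.frame(metabolite = names, shift_ppm = shifts,
                       amplitude = amps, lw_hz = lw, phase_deg = 0),
            nucleus)
}

## Total ground-truth amplitude per metabolite of a table.
totalAmplitudes <- function(table) {
  lines <- peakLines(table)
  vapply(metabolites(table), function(m)
    sum(lines$amplitude[lines$metabolite == m]), numeric(1))
}

## K well-separated damped exponentials for rank/exactness checks.
kLineTable <- function(K, nucleus = "P31") {
  shifts <- seq(-18, 8, length.out = K)
  PeakTable(data.frame(metabolite = paste0("M", seq_len(K)),
                       shift_ppm = shifts,
                       amplitude = seq(1, 2, length.out = K),
                       lw_hz = seq(15, 30, length.out = K),
                       phase_deg = 0),
            nucleus)
}

relErr <- function(x, y) {
  sqrt(sum(Mod(x - y)^2)) / sqrt(sum(Mod(y)^2))
}
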