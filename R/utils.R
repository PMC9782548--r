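## Internal numerical helpers shared across modules.

## Reorder an FFT output so frequencies run -floor(n/2) .. ceiling(n/2)-1 bins.
fftshift <- function(x) {
  n <- length(x)
  x[((seq_len(n) - 1L + ceiling(n / 2)) %% n) + 1L]
}

## Row reordering indices equivalent to fftshift followed by reversal, i.e.
## the mapping from raw fft() bin order to a decreasing-ppm axis.
.spectrumOrder <- function(n) {
  rev(((seq_len(n) - 1L + ceiling(n / 2)) %% n) + 1L)
}

## Frequency axis (Hz, increasing) matching fftshift() ordering.
.shiftedFreqAxis <- function(n, sw) {
  (seq_len(n) - 1L - floor(n / 2)) * sw / n
}

## Evaluate a block with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Per-replicate seed derived from a master seed by fixed arithmetic;
## kept strictly below 2^31.
deriveSeed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 1000003) * 2011 + 7 * as.numeric(index)) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stackReIm <- function(z) {
  if (is.matrix(z)) rbind(Re(z), Im(z)) else c(Re(z), Im(z))
}
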