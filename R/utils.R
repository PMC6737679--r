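`%||%` <- function(a, b) if (is.null(a)) b else a

clip_low <- function(x, lo) pmax(x, lo)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("zero-length direction vector")
  v / n
}

# Background threshold for MR foreground extraction: two-threshold (3-class)
# Otsu on a 128-bin histogram, returning the lower cut. The three classes
# capture air background, dark fibroglandular tissue and bright fat; the
# plain 2-class Otsu can land between the two tissue classes and clip FGT.
background_threshold <- function(x, nbins = 128L) {
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) stopf("cannot threshold a constant image")
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  w <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  cw <- c(0, cumsum(w))
  cm <- c(0, cumsum(w * mids))
  best <- -Inf
  best_a <- 1L
  for (a in 1:(nbins - 2L)) {
    w0 <- cw[a + 1L]
    m0 <- cm[a + 1L]
    if (w0 <= 0) next
    b <- (a + 1L):(nbins - 1L)
    w1 <- cw[b + 1L] - w0
    w2 <- 1 - w0 - w1
    m1 <- cm[b + 1L] - m0
    m2 <- cm[nbins + 1L] - m0 - m1
    v <- m0^2 / w0 + ifelse(w1 > 0, m1^2 / w1, 0) + ifelse(w2 > 0, m2^2 / w2, 0)
    j <- which.max(v)
    if (v[j] > best) { best <- v[j]; best_a <- a }
  }
  mids[best_a] + diff(r) / nbins / 2
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) stopf("cannot threshold a constant image")
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  w <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}
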