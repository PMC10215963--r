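## Internal numerical helpers. All time/interval arithmetic in the package
## uses the half-open convention: sample i (1-based) covers
## [(i-1)/rate, i/rate), so a run of samples s..e spans
## [(s-1)/rate, e/rate) and lasts (e - s + 1)/rate seconds.

.stop_input <- function(...) stop(..., call. = FALSE)

## Centered moving average with edge windows shrunk (never zero-padded).
.roll_mean_center <- function(x, half) {
  n <- length(x)
  if (half <= 0L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Means of every contiguous window of exactly w samples (length n - w + 1).
.roll_mean_width <- function(x, w) {
  n <- length(x)
  if (w > n) .stop_input("window longer than series")
  cs <- cumsum(c(0, x))
  (cs[seq(w, n) + 1L] - cs[seq_len(n - w + 1L)]) / w
}

## Maximal runs of TRUE, as an integer matrix with columns start, end
## (1-based, inclusive).
.logical_runs <- function(x) {
  if (length(x) == 0L || !any(x)) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  d <- diff(c(FALSE, x, FALSE))
  cbind(start = which(d == 1L), end = which(d == -1L) - 1L)
}

## Merge runs whose inter-run gap (in samples) is <= max_gap, iterated to a
## fixed point. A single left-to-right pass reaches the fixed point because
## merging only ever removes gaps, but the loop guards the contract.
.merge_runs <- function(runs, max_gap) {
  while (nrow(runs) > 1L) {
    gaps <- runs[-1L, 1L] - runs[-nrow(runs), 1L + 1L] - 1L
    if (!any(gaps <= max_gap)) break
    grp <- cumsum(c(TRUE, gaps > max_gap))
    runs <- cbind(start = as.integer(tapply(runs[, 1L], grp, min)),
                  end = as.integer(tapply(runs[, 2L], grp, max)))
  }
  runs
}

## Deterministic per-stream seed derivation so that adding streams never
## perturbs existing ones. Arithmetic kept inside the exact-double range.
.derive_seed <- function(master, k) {
  as.integer(((as.double(master) %% 2147483647) * 48271 + k * 962287 + 7) %%
               2147483647)
}

## Full-precision numeric formatting so that written tables re-read
## bit-identically.
.format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

## Deterministic CSV writer (no quoting, no row names, fixed numeric format).
.write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- .format_full(out[[j]])
  lines <- c(paste(names(out), collapse = ","),
             if (nrow(out)) do.call(paste, c(unname(out), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

.read_table <- function(path, comment = "#") {
  utils::read.csv(path, comment.char = comment, stringsAsFactors = FALSE)
}

## Intersection length of half-open intervals [a1,a2) and [b1,b2).
.interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}
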