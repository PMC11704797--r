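## Independent brute-force oracles, deliberately written with a different
## structure from the package implementation.

## mid-distribution empirical quantile by direct counting
oracle_quantile <- function(ref, x, log_transform = FALSE,
                            flip = FALSE) {
  if (log_transform) {
    ref <- log(ref)
    x <- log(x)
  }
  q <- (sum(ref < x) + 0.5 * sum(ref == x)) / length(ref)
  q <- min(1, max(0, q))
  if (flip) 1 - q else q
}

## CDP by exhaustive candidate/confirmation scan; `worse` is a logical
## vector saying whether each visit meets the endpoint's worsening rule.
oracle_cdp <- function(times, worse, confirm, strict = TRUE,
                       from_baseline = FALSE) {
  nv <- length(times)
  if (nv <= 1L) return(list(event = 0L, time = 0))
  starts <- if (from_baseline) seq_len(nv) else seq(2, nv)
  for (j in starts) {
    if (!worse[j]) next
    conf_idx <- 0L
    for (cc in seq(j, nv)) {
      if (times[cc] >= times[j] + confirm) {
        conf_idx <- cc
        break
      }
    }
    if (conf_idx == 0L) next
    span <- seq(min(j + 1L, conf_idx), conf_idx)
    confirmed <- if (strict) {
      all(worse[span]) || conf_idx == j
    } else {
      worse[conf_idx]
    }
    if (confirmed) return(list(event = 1L, time = times[j]))
  }
  list(event = 0L, time = times[nv])
}

## worsening rules restated independently
oracle_worse_edss <- function(values) {
  b <- values[1]
  req <- if (b < 3) 1 else if (b <= 5) 1 else if (b <= 6.5 && b >= 5.5) 0.5 else 0.5
  values >= b + req - 1e-9
}
oracle_worse_pct <- function(values, thr = 0.2) {
  values >= values[1] * (1 + thr) - 1e-9
}
oracle_worse_sdmt <- function(values) {
  b <- values[1]
  (b - values >= 3 - 1e-9) | (b - values >= 0.1 * b - 1e-9)
}
oracle_worse_edss6 <- function(values) values >= 6 - 1e-9

## full four-family enumeration against the oracle; returns mismatch count
## and the number of series checked
check_cdp_exhaustive <- function(max_len = 5) {
  times_all <- c(0, 3, 6, 9, 12)
  families <- list(
    edss = list(levels = c(3.0, 4.0, 5.5, 6.0, 6.5), confirm = 3,
                detect = function(tm, v, s) detect_cdp_edss(tm, v, strict = s),
                worse = oracle_worse_edss, from_baseline = FALSE),
    pct = list(levels = c(8, 10, 11.9, 12, 15), confirm = 3,
               detect = function(tm, v, s) detect_cdp_percent(tm, v, strict = s),
               worse = oracle_worse_pct, from_baseline = FALSE),
    sdmt = list(levels = c(40, 38, 37, 36, 20), confirm = 6,
                detect = function(tm, v, s) detect_cdp_sdmt(tm, v, strict = s),
                worse = oracle_worse_sdmt, from_baseline = FALSE),
    edss6 = list(levels = c(5.0, 5.5, 6.0, 6.5, 7.0), confirm = 3,
                 detect = function(tm, v, s) {
                   r <- detect_confirmed_edss6(tm, v, 0, 30, strict = s)
                   list(event = r$event, time = r$time_years * 12)
                 },
                 worse = oracle_worse_edss6, from_baseline = TRUE)
  )
  mismatches <- 0L
  checked <- 0L
  for (fam in families) {
    for (len in 2:max_len) {
      tm <- times_all[seq_len(len)]
      grid <- as.matrix(expand.grid(rep(list(fam$levels), len)))
      for (strict in c(TRUE, FALSE)) {
        for (i in seq_len(nrow(grid))) {
          v <- grid[i, ]
          got <- fam$detect(tm, v, strict)
          want <- oracle_cdp(tm, fam$worse(v), fam$confirm, strict,
                             fam$from_baseline)
          if (got$event != want$event || abs(got$time - want$time) > 1e-9) {
            mismatches <- mismatches + 1L
          }
          checked <- checked + 1L
        }
      }
    }
  }
  list(mismatches = mismatches, checked = checked)
}
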