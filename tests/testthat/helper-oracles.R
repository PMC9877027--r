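# Brute-force reference implementations, kept deliberately naive (explicit
# loops and dictionaries) and independent of the package's vectorized paths.

brute_zonal_mean <- function(values, units) {
  id <- units$raster$values
  v <- values$values
  acc <- list()
  for (i in seq_len(nrow(id))) {
    for (j in seq_len(ncol(id))) {
      u <- id[i, j]
      if (!is.na(u) && !is.na(v[i, j])) {
        key <- as.character(u)
        acc[[key]] <- c(acc[[key]], v[i, j])
      }
    }
  }
  out <- data.frame(unit_id = units$units$unit_id)
  out$mean <- NA_real_
  out$n_pixels <- 0L
  for (key in names(acc)) {
    k <- which(out$unit_id == as.integer(key))
    out$mean[k] <- mean(acc[[key]])
    out$n_pixels[k] <- length(acc[[key]])
  }
  out
}

brute_unit_count <- function(eco, lc, con, excluded) {
  seen <- character()
  e <- eco$values; l <- lc$values; k <- con$values
  for (i in seq_len(nrow(e))) {
    for (j in seq_len(ncol(e))) {
      if (is.na(e[i, j]) || is.na(l[i, j]) || is.na(k[i, j])) next
      if (l[i, j] %in% excluded) next
      seen <- union(seen, paste(e[i, j], l[i, j], k[i, j]))
    }
  }
  length(seen)
}

brute_aggregate_mean <- function(fine, factor) {
  v <- fine$values
  out <- matrix(NA_real_, nrow(v) / factor, ncol(v) / factor)
  for (R in seq_len(nrow(out))) {
    for (C in seq_len(ncol(out))) {
      block <- v[((R - 1) * factor + 1):(R * factor),
                 ((C - 1) * factor + 1):(C * factor)]
      if (any(!is.na(block))) out[R, C] <- mean(block[!is.na(block)])
    }
  }
  out
}

brute_gap_fill <- function(pool_values, unit_table) {
  out <- as.data.frame(pool_values)
  meta <- as.data.frame(unit_table)
  for (r in seq_len(nrow(out))) {
    if (!is.na(out$value[r])) next
    me <- meta[meta$unit_id == out$unit_id[r], ]
    donors <- numeric()
    for (s in seq_len(nrow(out))) {
      if (s == r || is.na(pool_values$value[s])) next
      if (out$myc_type[s] != out$myc_type[r] ||
          out$growth_form[s] != out$growth_form[r]) next
      other <- meta[meta$unit_id == out$unit_id[s], ]
      if (other$ecoregion == me$ecoregion && other$continent == me$continent)
        donors <- c(donors, pool_values$value[s])
    }
    if (length(donors) > 0) out$value[r] <- mean(donors)
  }
  out
}

# random categorical world for the oracle-equivalence suite
random_world_layers <- function(seed, nr = 50, nc = 50) {
  set.seed(seed)
  mk <- function(codes, p_na = 0.05) {
    v <- matrix(sample(codes, nr * nc, replace = TRUE), nr, nc)
    v[matrix(stats::runif(nr * nc) < p_na, nr, nc)] <- NA
    raster_grid(v)
  }
  list(eco = mk(1:4), lc = mk(1:6), con = mk(1:2),
       values = raster_grid(matrix(stats::rnorm(nr * nc), nr, nc)))
}
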