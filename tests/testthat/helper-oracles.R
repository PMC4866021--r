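# Independent oracles, deliberately loop-coded and separate from the package
# implementations they check.

# running-sum enrichment statistic, step by step
oracle_es <- function(values, hits, p) {
  n <- length(values)
  nh <- sum(hits)
  w <- if (p == 0) rep(1, n) else abs(values)^p
  nr <- sum(w[hits])
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      cur <- cur + if (nr > 0) w[i] / nr else 1 / nh
    } else {
      cur <- cur - 1 / (n - nh)
    }
    run[i] <- cur
  }
  best <- 1
  for (i in seq_len(n)) {
    # tolerant comparison so exact-arithmetic ties resolve to the earliest
    # position regardless of accumulation order (plain doubles here vs
    # long-double cumsum in the implementation)
    if (abs(run[i]) > abs(run[best]) + 1e-12) best <- i
  }
  list(es = run[best], pos = best, run = run)
}

# set-comprehension re-implementation of the record-level filters
oracle_filter_records <- function(records, cfg) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ok <- r$source_db %in% cfg$selected_dbs
    if (!identical(cfg$species, "any")) ok <- ok && r$species == cfg$species
    if (!identical(cfg$methods, "all")) {
      m <- tolower(trimws(r$methods[[1]]))
      ok <- ok && any(m %in% tolower(trimws(cfg$methods)))
    }
    if (r$source_db == "starbase") {
      ok <- ok && r$clip_support >= cfg$starbase_min_clip
    }
    keep[i] <- ok
  }
  records[keep, ]
}

# random small ranked lists for property tests
random_ranked <- function(n, signed = FALSE) {
  v <- stats::rnorm(n)
  if (!signed) v <- abs(v) + 0.1
  tibble::tibble(accession = paste0("G", seq_len(n)),
                 rank_value = sort(v, decreasing = TRUE))
}
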