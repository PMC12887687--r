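# Independent oracles, written as plain brute force from the stated rules so
# they share no code with the implementation paths they check.

# Brute-force diagnosis resolver: count categories with nested loops and
# apply the resolution rules literally.
oracle_resolve <- function(codes, dates) {
  if (length(codes) == 0L) return(list(label = "none", index_date = as.Date(NA)))
  dates <- as.Date(dates)
  up <- toupper(gsub("\\.", "", codes))
  for (cd in up) if (substr(cd, 1, 3) == "Q90") {
    return(list(label = "excluded", index_date = as.Date(NA)))
  }
  sets <- list(
    AD = c("F00", "F001", "F002", "F009", "G30", "G301", "G308", "G309"),
    VaD = c("F01", "F011", "F012", "F013", "F018", "F019"),
    Other = c("F02", "F021", "F022", "F023", "F024", "F028", "G31"),
    Unspecified = "F03", MCI = "F067")
  cat_of <- function(cd) {
    for (k in names(sets)) {
      if (cd %in% sets[[k]]) return(k)
      if (nchar(cd) == 4 && substr(cd, 1, 3) %in% sets[[k]]) return(k)
    }
    "none"
  }
  cats <- vapply(up, cat_of, "")
  keep <- cats != "none"
  if (!any(keep)) return(list(label = "none", index_date = as.Date(NA)))
  cats <- cats[keep]; dts <- dates[keep]
  if (length(unique(cats)) >= 4) {
    return(list(label = "excluded", index_date = as.Date(NA)))
  }
  tab <- sort(table(cats), decreasing = TRUE)
  tied <- names(tab)[tab == tab[1]]
  if (length(tied) > 1) {
    first_date <- sapply(tied, function(k) min(as.numeric(dts[cats == k])))
    tied <- tied[first_date == min(first_date)]
    prec <- c("AD", "VaD", "Other", "Unspecified", "MCI")
    winner <- prec[prec %in% tied][1]
  } else {
    winner <- tied
  }
  if (winner %in% c("AD", "VaD")) {
    list(label = winner, index_date = min(dts[cats == winner]))
  } else {
    list(label = "excluded", index_date = as.Date(NA))
  }
}

# Random dementia-code event list for resolution property tests.
random_event_list <- function(max_events = 6) {
  pool <- c("F00", "F001", "F009", "G30", "G309", "F01", "F011", "F019",
            "F02", "F021", "G31", "F03", "F067", "F05", "F050", "Q90",
            "I10", "E11", "J18")
  k <- sample.int(max_events, 1)
  codes <- sample(pool, k, replace = TRUE)
  dates <- as.Date("2005-01-01") + sample.int(5000, k, replace = TRUE)
  # dedupe to first instances like the readers do
  keep <- !duplicated(codes)
  list(codes = codes[keep], dates = dates[keep])
}

# Exhaustive Mann-Whitney permutation oracle: enumerate every assignment of
# the pooled values to the two groups with utils::combn.
oracle_mwu_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- abs(u_of(seq_len(n1)) - n1 * (N - n1) / 2)
  all_idx <- utils::combn(N, n1)
  devs <- abs(apply(all_idx, 2, u_of) - n1 * (N - n1) / 2)
  mean(devs >= obs - 1e-9)
}

# Brute-force degree centrality: count adjacency per node from the edge list.
oracle_degree_centrality <- function(nodes, edges) {
  if (length(nodes) < 2) return(stats::setNames(rep(0, length(nodes)), nodes))
  deg <- sapply(nodes, function(v) {
    sum(edges$u == v) + sum(edges$v == v)
  })
  stats::setNames(deg / (length(nodes) - 1), nodes)
}

# Small presence_matrix built directly from a binary matrix (bypasses the
# temporal layer) for network/stats unit tests.
pm_from_matrix <- function(M, window = "0-2 before", kind = "pre",
                           level = "code") {
  storage.mode(M) <- "integer"
  structure(list(status = M, window = window, kind = kind, level = level,
                 n = nrow(M)), class = "presence_matrix")
}
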