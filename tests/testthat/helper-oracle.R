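# Independent brute-force oracle for duplicate-citation and
# transcription-error detection: naive O(n^2) pairwise loops, base-R
# rounding, explicit breadth-first clustering.  Deliberately shares no
# code with the package internals.

oracle_near <- function(x, y, tol = 1e-9) {
  x == y || abs(x - y) <= tol * max(abs(x), abs(y))
}

# decimal half-up rounding to k significant figures, done on the printed
# decimal expansion (independent of the package's floating-point epsilon
# approach): take 15 decimal digits, keep k, carry if the next digit is >= 5
oracle_signif <- function(x, k) {
  if (is.na(x) || x == 0) return(x)
  s <- sprintf("%.14e", abs(x))
  mant <- sub("\\.", "", sub("e.*", "", s))   # 15 decimal digits
  ex <- as.integer(sub(".*e", "", s))
  keep <- as.numeric(substr(mant, 1, k))
  if (as.integer(substr(mant, k + 1, k + 1)) >= 5) keep <- keep + 1
  sign(x) * keep * 10^(ex - k + 1)
}

oracle_pair_match <- function(a, b) {
  if (oracle_near(a, b)) return(TRUE)
  for (k in 1:3) {
    if (oracle_near(a, oracle_signif(b, k)) ||
        oracle_near(oracle_signif(a, k), b)) {
      return(TRUE)
    }
  }
  FALSE
}

# the two-tier standard rounding rule, again via decimal strings
oracle_round_std <- function(x) {
  if (is.na(x) || x == 0) return(x)
  if (abs(x) < 10) return(oracle_signif(x, 3))
  ex <- as.integer(sub(".*e", "", sprintf("%.14e", abs(x))))
  oracle_signif(x, ex + 3)   # 2 decimal places
}

# rank of each member in document order: year ascending (NA last), then id
oracle_doc_rank <- function(doc, year) {
  ord <- order(ifelse(is.na(year), Inf, year), doc)
  rnk <- integer(length(ord))
  rnk[ord] <- seq_along(ord)
  rnk
}

oracle_duplicates <- function(members) {
  n <- nrow(members)
  if (n < 2) return(character())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (members$document_id[i] != members$document_id[j] &&
          oracle_pair_match(members$standard_value[i],
                            members$standard_value[j])) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  flagged <- logical(n)
  visited <- logical(n)
  for (s in seq_len(n)) {
    if (visited[s]) next
    # BFS component containing s
    comp <- s; frontier <- s; visited[s] <- TRUE
    while (length(frontier)) {
      nbr <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !visited)
      visited[nbr] <- TRUE
      comp <- c(comp, nbr); frontier <- nbr
    }
    if (length(comp) < 2) next
    rnk <- oracle_doc_rank(members$document_id[comp],
                           members$document_year[comp])
    earliest_doc <- members$document_id[comp][which.min(rnk)]
    flagged[comp[members$document_id[comp] != earliest_doc]] <- TRUE
  }
  members$record_id[flagged]
}

oracle_transcription <- function(members, decades = c(3, 6)) {
  n <- nrow(members)
  if (n < 2) return(character())
  rnk <- oracle_doc_rank(members$document_id, members$document_year)
  out <- character()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (members$document_id[i] == members$document_id[j]) next
      big <- max(members$standard_value[i], members$standard_value[j])
      small <- min(members$standard_value[i], members$standard_value[j])
      hit <- FALSE
      for (k in decades) {
        sc <- big / 10^k
        if (oracle_near(sc, small, tol = 1e-6) ||
            oracle_pair_match(sc, small) ||
            oracle_pair_match(oracle_round_std(sc), small)) hit <- TRUE
      }
      if (hit) out <- c(out, members$record_id[if (rnk[i] > rnk[j]) i else j])
    }
  }
  unique(out)
}

# random match-group generator used by the oracle-equivalence properties:
# a mix of independent values, exact/rounded cross-document citations and
# decade slips
random_group <- function(n, group_tag = "g") {
  docs <- paste0("D", sample(1:8, n, replace = TRUE))
  years <- 2000L + as.integer(sub("D", "", docs))
  vals <- round_standard_value(10^runif(n, -1, 5))
  for (i in seq_len(n)) {
    u <- runif(1)
    prev <- which(years[seq_len(i - 1)] < years[i])
    if (length(prev) && u < 0.25) {
      src <- sample(prev, 1)
      vals[i] <- if (runif(1) < 0.5) vals[src] else
        signif(vals[src], sample(1:3, 1))
    } else if (length(prev) && u < 0.35) {
      src <- sample(prev, 1)
      vals[i] <- round_standard_value(
        vals[src] * 10^(sample(c(3, 6), 1) * sample(c(-1, 1), 1)))
    }
  }
  tibble::tibble(
    group_id = 1L,
    record_id = paste0(group_tag, "_r", seq_len(n)),
    document_id = docs, document_year = years,
    standard_value = vals
  )
}
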