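# Independent oracles used across the suite. Each is deliberately written
# against the *stated semantics*, not against the package code paths it
# checks: a plain codon-walking translator, an affine-gap DP scorer, a
# string-rewriting module-definition evaluator, and brute-force recounts.

# -- codon-by-codon translator (bacterial code), no Biostrings ---------------
ORACLE_CODE_11 <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIIMTTTTNNKKSSRR",   # ATT..AGG
    "VVVVAAAADDEEGGGG"),  # GTT..GGG
    "")[[1]]
  codons <- as.vector(t(outer(bases, as.vector(t(outer(bases, bases, paste0))),
                              paste0)))
  stats::setNames(aas, codons)
})

oracle_translate <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  codons <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(ORACLE_CODE_11[codons])
  aa[is.na(aa)] <- "X"
  sub("\\*$", "", paste(aa, collapse = ""))
}

oracle_revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", nt), "")[[1]]), collapse = "")
}

# -- affine-gap global alignment score (gap of length L costs open + L*ext) --
oracle_nw_score <- function(a, b, sub, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -open - i * ext
  for (j in seq_len(m)) Iy[1, j + 1] <- -open - j * ext
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sub[av[i], bv[j]]
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# -- module definition evaluator by textual rewriting ------------------------
# Substitutes every K/M id with 1/0, reduces innermost parentheses to
# numeric literals, then evaluates the flat expression: space-separated
# steps averaged, comma alternatives maximized, +/- complexes boolean with
# '-' members ignored. Shares no code with the package parser/evaluator.
oracle_module_value <- function(def, kos) {
  s <- def
  ids <- unique(regmatches(s, gregexpr("[KM][0-9]{5}", s))[[1]])
  for (id in ids)
    s <- gsub(id, if (id %in% kos) "1" else "0", s, fixed = TRUE)
  s <- gsub("--", "1", s, fixed = TRUE)
  reduce_flat <- function(txt) {
    steps <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
    vals <- vapply(steps, function(st) {
      alts <- strsplit(st, ",", fixed = TRUE)[[1]]
      max(vapply(alts, function(cx) {
        m <- gregexpr("([+-]?)([0-9][.0-9]*)", cx)[[1]]
        toks <- regmatches(cx, list(m))[[1]]
        signs <- sub("^([+-]?).*$", "\\1", toks)
        nums <- as.numeric(sub("^[+-]?", "", toks))
        if (length(nums) == 1 && signs[1] != "-") return(nums[1])
        req <- nums[signs != "-"]
        if (!length(req)) 1 else as.numeric(all(req == 1))
      }, 0))
    }, 0)
    mean(vals)
  }
  repeat {
    m <- regexpr("\\(([^()]*)\\)", s)
    if (m == -1) break
    inner <- sub("^\\(", "", sub("\\)$", "", regmatches(s, m)))
    regmatches(s, m) <- format(reduce_flat(inner), digits = 15)
  }
  reduce_flat(s)
}

# random well-formed module definitions over a KO inventory
random_module_definition <- function(kos, max_steps = 4) {
  unit <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.55)
      return(sample(kos, 1))
    kind <- sample(c("alt", "complex", "optional", "group", "gap"), 1,
                   prob = c(0.3, 0.3, 0.15, 0.2, 0.05))
    if (kind == "gap") return("--")
    if (kind == "alt") {
      kids <- vapply(seq_len(sample(2:3, 1)), function(i) unit(depth - 1), "")
      kids <- ifelse(grepl(" ", kids), paste0("(", kids, ")"), kids)
      return(paste(kids, collapse = ","))
    }
    if (kind == "complex") {
      kids <- vapply(seq_len(sample(2:3, 1)), function(i) unit(depth - 1), "")
      kids <- ifelse(grepl("[ ,+]", kids), paste0("(", kids, ")"), kids)
      signs <- c("", sample(c("+", "-"), length(kids) - 1, replace = TRUE,
                            prob = c(0.8, 0.2)))
      return(paste0(signs, kids, collapse = ""))
    }
    if (kind == "optional") {
      k <- unit(0)
      return(paste0(sample(kos, 1), "-", k))
    }
    inner <- vapply(seq_len(sample(2:3, 1)), function(i) unit(depth - 1), "")
    paste0("(", paste(inner, collapse = " "), ")")
  }
  n_steps <- sample(seq_len(max_steps), 1)
  paste(vapply(seq_len(n_steps), function(i) unit(2), ""), collapse = " ")
}

# -- brute-force pan/core accumulation over explicit orderings ---------------
oracle_curves <- function(mat, orders) {
  G <- ncol(mat)
  pres <- mat >= 1
  pan <- core <- matrix(0, length(orders), G)
  for (oi in seq_along(orders)) {
    ord <- orders[[oi]]
    for (k in seq_len(G)) {
      cols <- pres[, ord[seq_len(k)], drop = FALSE]
      pan[oi, k] <- sum(apply(cols, 1, any))
      core[oi, k] <- sum(apply(cols, 1, all))
    }
  }
  list(pan_mean = colMeans(pan), core_mean = colMeans(core))
}

oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_permutations(n - 1L)) for (k in seq_len(n)) {
    q <- integer(n); q[k] <- n; q[-k] <- p
    out[[length(out) + 1L]] <- q
  }
  out
}

# -- partition utilities -----------------------------------------------------
canon_partition <- function(groups) {
  s <- lapply(groups, sort)
  unname(s[order(vapply(s, `[`, "", 1))])
}

rand_index <- function(a, b) {
  # a, b: named membership vectors over the same element set
  els <- names(a)
  stopifnot(setequal(els, names(b)))
  b <- b[els]
  agree <- 0; total <- 0
  for (i in seq_along(els)[-length(els)]) for (j in (i + 1):length(els)) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    agree <- agree + (same_a == same_b)
    total <- total + 1
  }
  unname(agree / total)
}

membership_of <- function(groups) {
  out <- character(0)
  for (g in names(groups)) out[groups[[g]]] <- g
  out
}
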