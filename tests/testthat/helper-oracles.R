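# Independent oracles used to cross-check the compiled search core.
# Everything here is written in plain R, separately from the package
# implementation, and favours clarity over speed.

# strip class/attributes from a filled matrix for comparison with oracles
bare_matrix <- function(m) structure(as.integer(m), dim = dim(m))

orc_comp <- function(x, y) {
  paste0(toupper(x), toupper(y)) %in% c("AT", "TA", "CG", "GC")
}

orc_comp_string <- function(s) chartr("ACGT", "TGCA", toupper(s))

# Minimum alignment penalty of every prefix pair by exhaustive recursion
# over all gapped alignments (no memoisation): an enumeration oracle for
# the DP fill.
oracle_align_matrix <- function(a, b, match = 0, mismatch = 1, gap = 1) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- Inf
    if (i > 0 && j > 0)
      best <- min(best, rec(i - 1, j - 1) +
                    if (orc_comp(A[i], B[j])) match else mismatch)
    if (i > 0) best <- min(best, rec(i - 1, j) + gap)
    if (j > 0) best <- min(best, rec(i, j - 1) + gap)
    best
  }
  M <- matrix(0L, length(A) + 1, length(B) + 1)
  for (i in 0:length(A))
    for (j in 0:length(B))
      M[i + 1, j + 1] <- rec(i, j)
  storage.mode(M) <- "integer"
  M
}

oracle_fill <- function(arm_a, arm_b, match = 0, mismatch = 1, gap = 1) {
  A <- strsplit(toupper(arm_a), "")[[1]]
  B <- strsplit(toupper(arm_b), "")[[1]]
  M <- matrix(0L, length(A) + 1, length(B) + 1)
  M[1, ] <- (0:length(B)) * gap
  M[, 1] <- (0:length(A)) * gap
  for (i in seq_along(A))
    for (j in seq_along(B))
      M[i + 1, j + 1] <- min(
        M[i, j] + if (orc_comp(A[i], B[j])) match else mismatch,
        M[i, j + 1] + gap,
        M[i + 1, j] + gap)
  M
}

# Unordered lexicographic pair of the consumed prefixes: the
# strand-equivariant content key used for residual tie-breaks.
orc_content_key <- function(arm_a, comp_b, r, c) {
  u <- substr(arm_a, 1, r)
  w <- substr(comp_b, 1, c)
  sort(c(u, w))
}

orc_key_less <- function(k1, k2) {
  if (k1[1] != k2[1]) return(k1[1] < k2[1])
  k1[2] < k2[2]
}

# Exhaustive start-cell scan with the documented tie-break chain.
oracle_select <- function(M, arm_a, arm_b, max_mismatch, min_stem) {
  na <- nchar(arm_a); nb <- nchar(arm_b)
  cb <- orc_comp_string(arm_b)
  best <- NULL
  for (r in seq_len(na)) {
    for (c in seq_len(nb)) {
      if (M[r + 1, c + 1] > max_mismatch) next
      if (min(r, c) < min_stem) next
      cand <- c(r, c)
      if (is.null(best)) { best <- cand; next }
      b_mn <- min(best); c_mn <- min(cand)
      if (c_mn != b_mn) { if (c_mn > b_mn) best <- cand; next }
      bv <- M[best[1] + 1, best[2] + 1]; cv <- M[r + 1, c + 1]
      if (cv != bv) { if (cv < bv) best <- cand; next }
      b_mx <- max(best); c_mx <- max(cand)
      if (c_mx != b_mx) { if (c_mx < b_mx) best <- cand; next }
      kc <- orc_content_key(toupper(arm_a), cb, r, c)
      kb <- orc_content_key(toupper(arm_a), cb, best[1], best[2])
      if (any(kc != kb)) { if (orc_key_less(kc, kb)) best <- cand; next }
      if (r < best[1]) best <- cand
    }
  }
  best # consumed lengths (r, c), or NULL
}

# Min-value traceback with diagonal preference and the strand-equivariant
# gap tie-break; returns NULL when the loop-closing rung is not a pair.
oracle_traceback <- function(M, arm_a, arm_b, r, c,
                             match = 0, mismatch = 1, gap = 1) {
  A <- strsplit(toupper(arm_a), "")[[1]]
  B <- strsplit(toupper(arm_b), "")[[1]]
  cb <- orc_comp_string(arm_b)
  ev <- character(0)
  while (r > 0 || c > 0) {
    here <- M[r + 1, c + 1]
    dval <- uval <- lval <- Inf
    dok <- uok <- lok <- FALSE
    if (r > 0 && c > 0) {
      s <- if (orc_comp(A[r], B[c])) match else mismatch
      dval <- M[r, c]; dok <- here == dval + s
    }
    if (r > 0) { uval <- M[r, c + 1]; uok <- here == uval + gap }
    if (c > 0) { lval <- M[r + 1, c]; lok <- here == lval + gap }
    mn <- min(c(if (dok) dval, if (uok) uval, if (lok) lval))
    if (dok && dval == mn) {
      ev <- c(if (orc_comp(A[r], B[c])) "P" else "M", ev)
      r <- r - 1; c <- c - 1
    } else if (uok && uval == mn && lok && lval == mn) {
      u <- substr(toupper(arm_a), 1, r); w <- substr(cb, 1, c)
      if (u <= w) { ev <- c("B", ev); r <- r - 1 }
      else { ev <- c("A", ev); c <- c - 1 }
    } else if (uok && uval == mn) {
      ev <- c("B", ev); r <- r - 1
    } else {
      ev <- c("A", ev); c <- c - 1
    }
  }
  if (ev[1] != "P") return(NULL)
  paste(ev, collapse = "")
}

oracle_find_at <- function(seq, loop_start, loop_end, params) {
  s <- toupper(seq); L <- nchar(s)
  a <- loop_start - 1
  ka <- min(a, params$max_stem)
  kb <- min(L - loop_end, params$max_stem)
  if (ka < params$min_stem || kb < params$min_stem) return(NULL)
  arm_a <- paste(rev(strsplit(substr(s, a - ka + 1, a), "")[[1]]),
                 collapse = "")
  arm_b <- substr(s, loop_end + 1, loop_end + kb)
  pen <- params$penalties
  M <- oracle_fill(arm_a, arm_b, pen$match, pen$mismatch, pen$gap)
  rc <- oracle_select(M, arm_a, arm_b, params$max_mismatch,
                      params$min_stem)
  if (is.null(rc)) return(NULL)
  ev <- oracle_traceback(M, arm_a, arm_b, rc[1], rc[2],
                         pen$match, pen$mismatch, pen$gap)
  if (is.null(ev)) return(NULL)
  data.frame(seq_id = "seq",
             left_start = a - rc[1] + 1, left_end = a,
             loop_start = loop_start, loop_end = loop_end,
             right_start = loop_end + 1, right_end = loop_end + rc[2],
             stem_len = min(rc), loop_len = loop_end - loop_start + 1,
             penalty = M[rc[1] + 1, rc[2] + 1],
             events = ev, stringsAsFactors = FALSE)
}

oracle_scan <- function(seq, params) {
  L <- nchar(seq)
  rows <- list()
  if (L >= 2 * params$min_stem + params$min_loop) {
    for (llen in params$min_loop:params$max_loop) {
      amax <- L - llen - params$min_stem
      if (amax < params$min_stem) next
      for (a in params$min_stem:amax) {
        h <- oracle_find_at(seq, a + 1, a + llen, params)
        if (!is.null(h)) rows[[length(rows) + 1]] <- h
      }
    }
  }
  if (!length(rows))
    return(data.frame(left_start = integer(0), right_end = integer(0),
                      penalty = integer(0)))
  h <- do.call(rbind, rows)
  # redundancy: same loop-closing rung; keep longest stem then lowest penalty
  key <- paste(h$left_end, h$right_start)
  h <- h[order(key, -h$stem_len, h$penalty), ]
  h <- h[!duplicated(paste(h$left_end, h$right_start)), ]
  h <- h[order(h$left_start, h$right_end, h$loop_start), ]
  rownames(h) <- NULL
  h
}

# Exhaustive enumeration of nested structures: maximum pair count oracle
# for the fallback fold.
oracle_max_pairs <- function(seq, min_loop = 3, rna = FALSE) {
  ch <- strsplit(toupper(chartr("u", "U", seq)), "")[[1]]
  ch[ch == "U"] <- "T"
  ok <- function(x, y) {
    orc_comp(x, y) || (rna && paste0(x, y) %in% c("GT", "TG"))
  }
  rec <- function(i, j) {
    if (i >= j || j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j)
      if (ok(ch[i], ch[k]))
        best <- max(best, 1 + rec(i + 1, k - 1) + rec(k + 1, j))
    best
  }
  if (length(ch) < 2) 0 else rec(1, length(ch))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# coordinate mirror of hit spans onto the reverse complement
mirror_spans <- function(h, L) {
  data.frame(left_start = L - h$right_end + 1, left_end = L - h$right_start + 1,
             loop_start = L - h$loop_end + 1, loop_end = L - h$loop_start + 1,
             right_start = L - h$left_end + 1, right_end = L - h$left_start + 1,
             penalty = h$penalty)
}
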