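# Independent brute-force oracle for evolution-model enumeration.
#
# Mechanics deliberately different from the package implementation: genomes
# are lists of copies carrying symbolic mutation tokens; every event choice
# (which physical copy is duplicated or lost) is enumerated exhaustively,
# and multiplicity consequences are read off by counting tokens in the final
# genomes. The package instead replays canonical shortest paths with
# ancestry-chain counting.

oracle_genome <- function(a, b) {
  copies <- list()
  for (i in seq_len(a)) copies[[length(copies) + 1]] <- list(allele = "A", tokens = character(0))
  for (i in seq_len(b)) copies[[length(copies) + 1]] <- list(allele = "B", tokens = character(0))
  copies
}

oracle_counts <- function(g) {
  al <- vapply(g, function(cp) cp$allele, character(1))
  c(sum(al == "A"), sum(al == "B"))
}

# deposit one fresh token on every copy (a mutation class per copy per epoch)
oracle_mutate <- function(g, tag) {
  for (i in seq_along(g)) g[[i]]$tokens <- c(g[[i]]$tokens, paste0(tag, "_", i))
  g
}

# all genomes reachable in exactly one event, enumerating every copy choice
oracle_step <- function(g, cap = 4) {
  out <- list()
  for (i in seq_along(g)) {                         # duplicate copy i
    g2 <- g; g2[[length(g2) + 1]] <- g[[i]]
    if (max(oracle_counts(g2)) <= cap) out[[length(out) + 1]] <- g2
  }
  for (i in seq_along(g)) {                         # lose copy i
    out[[length(out) + 1]] <- g[-i]
  }
  if (length(g) > 0) {                              # whole-genome doubling
    g2 <- c(g, g)
    if (max(oracle_counts(g2)) <= cap) out[[length(out) + 1]] <- g2
  }
  out
}

# all genomes reaching labelled state `target`, over all shortest paths,
# with a fresh token layer deposited before every event
oracle_reach <- function(g0, target, max_len = 4, tag = "e") {
  if (identical(oracle_counts(g0), target)) return(list(list(g = g0, len = 0L)))
  frontier <- list(g0)
  for (len in seq_len(max_len)) {
    nxt <- list(); hits <- list()
    for (g in frontier) {
      g <- oracle_mutate(g, paste0(tag, len))
      for (g2 in oracle_step(g)) {
        if (identical(oracle_counts(g2), target)) {
          hits[[length(hits) + 1]] <- list(g = g2, len = len)
        } else {
          nxt[[length(nxt) + 1]] <- g2
        }
      }
    }
    if (length(hits) > 0) return(hits)
    frontier <- nxt
    if (length(frontier) == 0) return(NULL)
  }
  NULL
}

oracle_token_counts <- function(g) {
  toks <- unlist(lapply(g, function(cp) cp$tokens))
  if (length(toks) == 0) return(integer(0))
  table(toks)
}

# multiplicity signature of one concrete scenario
oracle_signature <- function(topology, shared_pairs, priv1, priv2) {
  sp <- unique(shared_pairs[shared_pairs[, 1] + shared_pairs[, 2] > 0, , drop = FALSE])
  sp <- sp[order(sp[, 1], sp[, 2]), , drop = FALSE]
  paste(topology,
        paste(apply(sp, 1, paste, collapse = ","), collapse = ";"),
        paste(sort(unique(priv1[priv1 > 0])), collapse = ","),
        paste(sort(unique(priv2[priv2 > 0])), collapse = ","), sep = "|")
}

# token multiplicities of `tokens` in genome g (0 when absent)
oracle_mult <- function(g, tokens) {
  counts <- oracle_token_counts(g)
  out <- integer(length(tokens))
  present <- tokens %in% names(counts)
  out[present] <- as.integer(counts[tokens[present]])
  out
}

oracle_models <- function(state1, state2, ancestor = c(1L, 1L)) {
  parse <- function(x) as.integer(strsplit(x, ":")[[1]])
  s1 <- parse(state1); s2 <- parse(state2)
  labelled <- function(s) unique(list(s, rev(s)))
  sigs <- character(0)

  # branching: deposit ancestral tokens, then evolve two arms independently
  for (l1 in labelled(s1)) for (l2 in labelled(s2)) {
    g0 <- oracle_mutate(oracle_genome(ancestor[1], ancestor[2]), "anc")
    anc_tokens <- unlist(lapply(g0, function(cp) cp$tokens))
    r1 <- oracle_reach(g0, l1)
    r2 <- oracle_reach(g0, l2)
    if (is.null(r1) || is.null(r2)) next
    for (a in r1) for (b in r2) {
      shared <- cbind(oracle_mult(a$g, anc_tokens), oracle_mult(b$g, anc_tokens))
      own1 <- setdiff(unlist(lapply(a$g, `[[`, "tokens")), anc_tokens)
      own2 <- setdiff(unlist(lapply(b$g, `[[`, "tokens")), anc_tokens)
      # post-split residence in the ancestral state also yields m = 1 privates
      priv1 <- c(1L, oracle_mult(a$g, own1))
      priv2 <- c(1L, oracle_mult(b$g, own2))
      sigs <- c(sigs, oracle_signature("branching", shared, priv1, priv2))
    }
  }

  # linear: evolve to the intermediate, freeze one clone, continue the other
  for (dir in c("12", "21")) {
    li <- if (dir == "12") labelled(s1) else labelled(s2)
    lt <- if (dir == "12") labelled(s2) else labelled(s1)
    cand <- list()
    for (lm in li) for (le in lt) {
      g0 <- oracle_mutate(oracle_genome(ancestor[1], ancestor[2]), "anc")
      ra <- oracle_reach(g0, lm)
      if (is.null(ra)) next
      for (a in ra) {
        g_mid <- oracle_mutate(a$g, "mid")   # mutations while resident in mid
        rb <- oracle_reach(g_mid, le, tag = "f")
        if (is.null(rb)) next
        for (b in rb) {
          cand[[length(cand) + 1]] <- list(g_mid = g_mid, g_tip = b$g,
                                           total = a$len + b$len)
        }
      }
    }
    if (length(cand) == 0) next
    tot <- vapply(cand, function(x) x$total, numeric(1))
    for (cc in cand[tot == min(tot)]) {
      mid_tokens <- unique(unlist(lapply(cc$g_mid, `[[`, "tokens")))
      shared <- cbind(oracle_mult(cc$g_mid, mid_tokens),
                      oracle_mult(cc$g_tip, mid_tokens))
      tip_tokens <- setdiff(unlist(lapply(cc$g_tip, `[[`, "tokens")), mid_tokens)
      priv_mid <- 1L
      priv_tip <- c(1L, oracle_mult(cc$g_tip, tip_tokens))
      if (dir == "12") {
        sigs <- c(sigs, oracle_signature("linear", shared, priv_mid, priv_tip))
      } else {
        sigs <- c(sigs, oracle_signature("linear", shared[, c(2, 1), drop = FALSE],
                                         priv_tip, priv_mid))
      }
    }
  }
  sort(unique(sigs))
}

# package models rendered in the same signature form
package_signatures <- function(models) {
  if (nrow(models) == 0) return(character(0))
  sigs <- vapply(seq_len(nrow(models)), function(i) {
    sh <- as.matrix(models$shared_multiplicities[[i]][, c("m1", "m2")])
    oracle_signature(models$topology[i], sh,
                     models$private1[[i]], models$private2[[i]])
  }, character(1))
  sort(unique(sigs))
}
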