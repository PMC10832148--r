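#' Enumerate evolution models relating two subclonal copy states
#'
#' Two subclones observed with allele-specific states `state1` and `state2`
#' can be related through an unobserved ancestor (default a diploid
#' heterozygous 1:1 cell) either by branching -- both subclones descend
#' independently from the ancestor -- or linearly -- one subclone descends
#' from the other. The copy-state path of each lineage is built from
#' single-allele events (gain or loss of one copy of one parental allele)
#' plus a whole-genome-doubling step, and only shortest paths are retained;
#' for linear models, only the labelled variant(s) with the minimal total
#' event count across both legs survive.
#'
#' Because the two parental alleles are tracked separately, states such as
#' 2:1 appear in two labelled variants (AAB and ABB); models that amplify
#' different parental alleles predict different shared-mutation peaks and are
#' kept as distinct models (mirrored allelic imbalance), while paths with
#' identical multiplicity consequences are collapsed.
#'
#' For every model the multiplicity consequences are computed by replaying
#' the event path over physical chromosome copies: a mutation acquired on a
#' copy is inherited by all later duplications of that copy, so a shared
#' mutation acquired before the lineages separate carries a multiplicity
#' pair `(m1, m2)` (its copy number in each subclone), and mutations private
#' to a subclone carry the multiplicities achievable after the split.
#'
#' @param state1,state2 Karyotype strings `"nA:nB"` with `max(nA, nB) <= 2`
#'   (simple states; mirrored forms such as `"1:2"` are accepted).
#' @param ancestor Karyotype string of the unobserved ancestor (default
#'   `"1:1"`).
#' @return A tibble with one row per distinct model: `model_id`, `topology`
#'   (`"branching"` or `"linear"`), `description` (e.g. `"AB -> AAB | BB"`),
#'   `state1`, `state2`, `n_events`, and list-columns
#'   `shared_multiplicities` (tibble of `m1`, `m2` pairs), `private1`,
#'   `private2` (integer multiplicity sets). An unreachable configuration
#'   simply contributes no row.
#' @examples
#' enumerate_evolution_models("2:1", "2:0")  # 2 branching + 1 linear model
#' @export
enumerate_evolution_models <- function(state1, state2, ancestor = "1:1") {
  s1 <- parse_karyotype(state1)
  s2 <- parse_karyotype(state2)
  anc <- parse_karyotype(ancestor)
  for (s in list(s1, s2)) {
    if (max(s) > 2) {
      stop("Subclonal QC supports simple states only (allele counts <= 2).", call. = FALSE)
    }
  }

  labelled <- function(s) unique(list(s, rev(s)))
  models <- list()

  # branching: ancestor -> l1 | l2
  for (l1 in labelled(s1)) for (l2 in labelled(s2)) {
    p1 <- shortest_event_paths(anc, l1)
    p2 <- shortest_event_paths(anc, l2)
    if (is.null(p1) || is.null(p2)) next
    for (e1 in p1) for (e2 in p2) {
      models[[length(models) + 1]] <-
        branching_model(anc, l1, l2, e1, e2)
    }
  }

  # linear: ancestor -> intermediate -> tip; both observed orders
  for (dir in c("12", "21")) {
    li <- if (dir == "12") labelled(s1) else labelled(s2)
    lt <- if (dir == "12") labelled(s2) else labelled(s1)
    cands <- list()
    for (lm in li) for (le in lt) {
      pa <- shortest_event_paths(anc, lm)
      if (is.null(pa)) next
      pb <- shortest_event_paths(lm, le)
      if (is.null(pb)) next
      for (ea in pa) for (eb in pb) {
        cands[[length(cands) + 1]] <- list(mid = lm, tip = le, ea = ea, eb = eb,
                                           total = length(ea) + length(eb))
      }
    }
    if (length(cands) == 0) next
    tot <- vapply(cands, function(x) x$total, numeric(1))
    for (cand in cands[tot == min(tot)]) {
      models[[length(models) + 1]] <-
        linear_model(anc, cand$mid, cand$tip, cand$ea, cand$eb,
                     intermediate_is_clone1 = (dir == "12"))
    }
  }

  if (length(models) == 0) {
    return(tibble::tibble(
      model_id = integer(), topology = character(), description = character(),
      state1 = character(), state2 = character(), n_events = integer(),
      shared_multiplicities = list(), private1 = list(), private2 = list()
    ))
  }

  out <- dplyr::bind_rows(models)
  out$state1 <- state1
  out$state2 <- state2
  # collapse models with identical multiplicity consequences
  sig <- vapply(seq_len(nrow(out)), function(i) {
    sh <- out$shared_multiplicities[[i]]
    sh <- sh[order(sh$m1, sh$m2), , drop = FALSE]
    paste(out$topology[i],
          paste(sh$m1, sh$m2, sep = ",", collapse = ";"),
          paste(sort(out$private1[[i]]), collapse = ","),
          paste(sort(out$private2[[i]]), collapse = ","), sep = "|")
  }, character(1))
  out <- out[!duplicated(sig), , drop = FALSE]
  out$model_id <- seq_len(nrow(out))
  out
}

# ---- labelled copy-state graph ---------------------------------------------

# events: "gA", "gB", "lA", "lB", "wgd"; states c(a, b), counts capped at 4
apply_event <- function(s, ev, cap = 4L) {
  out <- switch(ev,
    gA  = if (s[1] >= 1) s + c(1L, 0L) else NULL,
    gB  = if (s[2] >= 1) s + c(0L, 1L) else NULL,
    lA  = if (s[1] >= 1) s - c(1L, 0L) else NULL,
    lB  = if (s[2] >= 1) s - c(0L, 1L) else NULL,
    wgd = if (sum(s) >= 1) 2L * s else NULL
  )
  if (!is.null(out) && max(out) > cap) out <- NULL
  out
}

# all shortest event sequences from labelled state `from` to `to`;
# NULL when unreachable (a lost allele cannot be regained)
shortest_event_paths <- function(from, to, max_len = 6L) {
  if (identical(from, to)) return(list(character(0)))
  events <- c("gA", "gB", "lA", "lB", "wgd")
  frontier <- list(list(s = from, path = character(0)))
  seen_depth <- list()
  for (depth in seq_len(max_len)) {
    nxt <- list()
    hits <- list()
    for (node in frontier) {
      for (ev in events) {
        s2 <- apply_event(node$s, ev)
        if (is.null(s2)) next
        path2 <- c(node$path, ev)
        if (identical(s2, to)) {
          hits[[length(hits) + 1]] <- path2
        } else {
          key <- paste(s2, collapse = ",")
          d <- seen_depth[[key]]
          if (is.null(d) || d >= depth) {   # keep all shortest continuations
            seen_depth[[key]] <- depth
            nxt[[length(nxt) + 1]] <- list(s = s2, path = path2)
          }
        }
      }
    }
    if (length(hits) > 0) return(hits)
    frontier <- nxt
    if (length(frontier) == 0) return(NULL)
  }
  NULL
}

# ---- physical-copy replay ---------------------------------------------------

# Replays an event sequence over physical chromosome copies. Returns the
# bookkeeping needed to count, for a mutation acquired on copy `c` during
# epoch `e` (after event `e`, before event `e+1`), how many copies of a later
# snapshot carry it.
replay_path <- function(anc, events) {
  n0 <- sum(anc)
  allele <- c(rep("A", anc[1]), rep("B", anc[2]))
  parent <- rep(NA_integer_, n0)
  birth <- rep(0L, n0)
  alive <- seq_len(n0)
  snapshots <- list(alive)                 # snapshots[[e + 1]] = alive set in epoch e
  for (t in seq_along(events)) {
    ev <- events[t]
    if (ev == "wgd") {
      for (cp in alive) {
        allele <- c(allele, allele[cp]); parent <- c(parent, cp); birth <- c(birth, t)
        alive <- c(alive, length(allele))
      }
    } else {
      which_allele <- substr(ev, 2, 2)
      pool <- alive[allele[alive] == which_allele]
      if (length(pool) == 0) stop("Invalid path replay.", call. = FALSE)
      cp <- pool[1]
      if (substr(ev, 1, 1) == "g") {
        allele <- c(allele, allele[cp]); parent <- c(parent, cp); birth <- c(birth, t)
        alive <- c(alive, length(allele))
      } else {
        alive <- setdiff(alive, cp)
      }
    }
    snapshots[[t + 1]] <- alive
  }
  list(allele = allele, parent = parent, birth = birth, snapshots = snapshots)
}

# copies in `final_set` carrying a mutation acquired on copy `c` in epoch `e`
carrier_count <- function(rep_obj, c, e, final_set) {
  n <- 0L
  for (d in final_set) {
    cur <- d
    ok <- FALSE
    repeat {
      if (cur == c) { ok <- TRUE; break }
      if (is.na(rep_obj$parent[cur]) || rep_obj$birth[cur] <= e) break
      cur <- rep_obj$parent[cur]
    }
    if (ok) n <- n + 1L
  }
  n
}

state_string <- function(s) {
  paste0(strrep("A", s[1]), strrep("B", s[2]))
}

branching_model <- function(anc, l1, l2, events1, events2) {
  # shared mutations sit on ancestral copies; each arm is replayed separately
  # from the same ancestral copy ids
  r1 <- replay_path(anc, events1)
  r2 <- replay_path(anc, events2)
  anc_ids <- seq_len(sum(anc))
  fin1 <- r1$snapshots[[length(r1$snapshots)]]
  fin2 <- r2$snapshots[[length(r2$snapshots)]]
  shared <- tibble::tibble(
    m1 = vapply(anc_ids, function(c) carrier_count(r1, c, 0L, fin1), integer(1)),
    m2 = vapply(anc_ids, function(c) carrier_count(r2, c, 0L, fin2), integer(1))
  )
  shared <- dplyr::distinct(shared[shared$m1 + shared$m2 > 0, , drop = FALSE])
  tibble::tibble(
    model_id = NA_integer_, topology = "branching",
    description = paste0(state_string(anc), " -> ", state_string(l1), " | ", state_string(l2)),
    state1 = NA_character_, state2 = NA_character_,
    n_events = length(events1) + length(events2),
    shared_multiplicities = list(shared),
    private1 = list(private_multiplicities(r1, post_epoch = 0L)),
    private2 = list(private_multiplicities(r2, post_epoch = 0L))
  )
}

linear_model <- function(anc, mid, tip, events_a, events_b, intermediate_is_clone1) {
  rp <- replay_path(anc, c(events_a, events_b))
  na <- length(events_a)
  snap_mid <- rp$snapshots[[na + 1]]                    # intermediate clone freezes here
  snap_tip <- rp$snapshots[[length(rp$snapshots)]]
  # shared classes: mutations in epochs 0..na (up to residence in the
  # intermediate state, before the tip lineage separates)
  shared <- list()
  for (e in 0:na) {
    for (cp in rp$snapshots[[e + 1]]) {
      shared[[length(shared) + 1]] <- c(
        carrier_count(rp, cp, e, snap_mid),
        carrier_count(rp, cp, e, snap_tip)
      )
    }
  }
  sh <- dplyr::distinct(tibble::tibble(
    m_mid = vapply(shared, `[`, integer(1), 1),
    m_tip = vapply(shared, `[`, integer(1), 2)
  ))
  sh <- sh[sh$m_mid + sh$m_tip > 0, , drop = FALSE]
  # private: intermediate clone acquires nothing after freezing (m = 1);
  # tip clone accumulates over epochs na..end
  priv_mid <- 1L
  priv_tip <- integer(0)
  for (e in na:(length(rp$snapshots) - 1)) {
    for (cp in rp$snapshots[[e + 1]]) {
      m <- carrier_count(rp, cp, e, snap_tip)
      if (m > 0) priv_tip <- union(priv_tip, m)
    }
  }
  if (intermediate_is_clone1) {
    shared_tbl <- tibble::tibble(m1 = sh$m_mid, m2 = sh$m_tip)
    p1 <- priv_mid; p2 <- sort(priv_tip)
    desc <- paste0(state_string(anc), " -> ", state_string(mid), " -> ", state_string(tip))
  } else {
    shared_tbl <- tibble::tibble(m1 = sh$m_tip, m2 = sh$m_mid)
    p1 <- sort(priv_tip); p2 <- priv_mid
    desc <- paste0(state_string(anc), " -> ", state_string(mid), " -> ", state_string(tip),
                   " (clone 2 ancestral)")
  }
  tibble::tibble(
    model_id = NA_integer_, topology = "linear", description = desc,
    state1 = NA_character_, state2 = NA_character_,
    n_events = length(events_a) + length(events_b),
    shared_multiplicities = list(shared_tbl),
    private1 = list(p1), private2 = list(p2)
  )
}

private_multiplicities <- function(rep_obj, post_epoch) {
  fin <- rep_obj$snapshots[[length(rep_obj$snapshots)]]
  out <- integer(0)
  for (e in post_epoch:(length(rep_obj$snapshots) - 1)) {
    for (cp in rep_obj$snapshots[[e + 1]]) {
      m <- carrier_count(rep_obj, cp, e, fin)
      if (m > 0) out <- union(out, m)
    }
  }
  sort(out)
}
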