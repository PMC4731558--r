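# Serial Kingman coalescent with instantaneous population splits (no
# migration) and optional piecewise-constant size changes. Time runs backwards
# in generations; gene copies within a population of diploid size Ne coalesce
# at rate choose(k,2) / (2*Ne), i.e. 2*Ne gene copies per population.

#' Define a demographic scenario
#'
#' A rooted history of populations connected by split events. Looking forward
#' in time each non-root population originates from its source population at
#' time `t`; looking backward (coalescent view) its lineages merge into the
#' source at `t`.
#'
#' @param populations character vector of population labels; the first label
#'   without an origin event is the root.
#' @param events data frame with columns `time` (generations before present),
#'   `derived`, `source`; one row per split. May have zero rows for a single
#'   population.
#' @param ne named numeric vector of diploid effective sizes, one per
#'   population.
#' @param id optional scenario identifier.
#' @return An object of class `scenario`.
#' @export
scenario <- function(populations, events, ne, id = "scenario") {
  populations <- as.character(populations)
  if (is.null(events)) events <- data.frame(time = numeric(0),
                                            derived = character(0),
                                            source = character(0))
  events <- as.data.frame(events)
  if (nrow(events)) {
    events$derived <- as.character(events$derived)
    events$source <- as.character(events$source)
    if (any(events$time <= 0)) stop("event times must be positive")
    if (anyDuplicated(events$derived))
      stop("each population may have only one origin")
    if (!all(c(events$derived, events$source) %in% populations))
      stop("event populations not in population list")
  }
  roots <- setdiff(populations, events$derived)
  if (length(roots) != 1)
    stop("events must form a tree with a single root population (found roots: ",
         paste(roots, collapse = ", "), ")")
  if (!all(populations %in% names(ne)))
    stop("ne must name every population")
  if (any(ne[populations] <= 0)) stop("Ne must be positive")
  structure(list(populations = populations,
                 events = events[order(events$time), , drop = FALSE],
                 ne = ne[populations], root = roots, id = id),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario", x$id, "-", length(x$populations), "populations, root",
      x$root, "\n")
  if (nrow(x$events))
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  t=%g: %s <- %s\n", x$events$time[i], x$events$source[i],
                  x$events$derived[i]))
  invisible(x)
}

# Simulate one genealogy. sample_sizes: named integer vector of GENE COPIES
# per population. size_changes: optional data.frame(time, pop, ne) of
# piecewise-constant diploid sizes (applies from `time` backwards).
# Returns list(n_tips, parent, length, tip_pop): parent/length indexed by node
# (tips 1..n, internal nodes n+1..2n-1, root parent = 0). Parents always
# carry a higher node index than their children (coalescence order), which
# downstream mutation placement relies on.
sim_genealogy <- function(sample_sizes, scen, size_changes = NULL) {
  pops <- scen$populations
  P <- length(pops)
  k <- sample_sizes[pops]
  k[is.na(k)] <- 0L
  n <- as.integer(sum(k))
  if (n < 1) stop("no samples")
  if (any(k > 4 * max(scen$ne)))
    stop("parameter error: sample size exceeds 2*Ne limit")
  parent <- integer(2 * n - 1)
  blen <- numeric(2 * n - 1)
  node_time <- numeric(2 * n - 1)
  tip_pop <- rep(pops, times = k)
  # per-population active-lineage arrays with swap-removal
  members <- matrix(0L, n, P)
  cnt <- integer(P)
  idx0 <- 0L
  for (p in seq_len(P)) {
    if (k[p] > 0) members[seq_len(k[p]), p] <- idx0 + seq_len(k[p])
    cnt[p] <- as.integer(k[p])
    idx0 <- idx0 + as.integer(k[p])
  }
  ne_now <- unname(scen$ne)
  # event agenda as parallel vectors
  ev_t <- numeric(0); ev_type <- integer(0); ev_a <- integer(0)
  ev_b <- integer(0); ev_ne <- numeric(0)
  if (nrow(scen$events)) {
    ev_t <- scen$events$time
    ev_type <- rep(1L, length(ev_t))
    ev_a <- match(scen$events$derived, pops)
    ev_b <- match(scen$events$source, pops)
    ev_ne <- rep(NA_real_, length(ev_t))
  }
  if (!is.null(size_changes)) {
    sc <- as.data.frame(size_changes)
    ev_t <- c(ev_t, sc$time)
    ev_type <- c(ev_type, rep(2L, nrow(sc)))
    ev_a <- c(ev_a, match(sc$pop, pops))
    ev_b <- c(ev_b, rep(NA_integer_, nrow(sc)))
    ev_ne <- c(ev_ne, sc$ne)
  }
  if (length(ev_t)) {
    # tie-break equal-time splits by tree depth (deepest derived first), so
    # a population always empties before its own origin event fires
    depth <- setNames(integer(length(pops)), pops)
    if (nrow(scen$events)) {
      for (p in pops) {
        d <- 0L; cur <- p
        while (cur %in% scen$events$derived) {
          cur <- scen$events$source[match(cur, scen$events$derived)]
          d <- d + 1L
        }
        depth[p] <- d
      }
    }
    key2 <- ifelse(ev_type == 1L, -depth[pops[ev_a]], 0L)
    o <- order(ev_t, key2)
    ev_t <- ev_t[o]; ev_type <- ev_type[o]; ev_a <- ev_a[o]
    ev_b <- ev_b[o]; ev_ne <- ev_ne[o]
  }
  t_now <- 0
  next_node <- n + 1L
  ev <- 1L
  n_ev <- length(ev_t)
  total_active <- n
  while (total_active > 1L) {
    t_next <- if (ev <= n_ev) ev_t[ev] else Inf
    repeat {
      rates <- cnt * (cnt - 1) / 2 / (2 * ne_now)
      tot <- sum(rates)
      if (tot > 0) {
        w <- rexp(1, tot)
      } else {
        if (is.infinite(t_next))
          stop("internal error: uncoalesced lineages with no pending events")
        w <- Inf
      }
      if (t_now + w >= t_next) { t_now <- t_next; break }
      t_now <- t_now + w
      p <- if (P == 1) 1L else {
        u <- runif(1) * tot
        pp <- 1L
        acc <- rates[1]
        while (acc < u && pp < P) { pp <- pp + 1L; acc <- acc + rates[pp] }
        pp
      }
      m <- cnt[p]
      i <- 1L + as.integer(runif(1) * m)
      j <- 1L + as.integer(runif(1) * (m - 1L))
      if (j >= i) j <- j + 1L
      a <- members[i, p]; b <- members[j, p]
      node <- next_node; next_node <- next_node + 1L
      node_time[node] <- t_now
      parent[a] <- node; parent[b] <- node
      blen[a] <- t_now - node_time[a]
      blen[b] <- t_now - node_time[b]
      members[i, p] <- node
      members[j, p] <- members[m, p]
      cnt[p] <- m - 1L
      total_active <- total_active - 1L
      if (total_active == 1L) break
    }
    if (total_active == 1L) break
    if (ev <= n_ev && t_now >= ev_t[ev]) {
      if (ev_type[ev] == 1L) {
        ia <- ev_a[ev]; ib <- ev_b[ev]
        if (cnt[ia] > 0) {
          members[cnt[ib] + seq_len(cnt[ia]), ib] <- members[seq_len(cnt[ia]), ia]
          cnt[ib] <- cnt[ib] + cnt[ia]
          cnt[ia] <- 0L
        }
      } else {
        ne_now[ev_a[ev]] <- ev_ne[ev]
      }
      ev <- ev + 1L
    }
  }
  list(n_tips = n, parent = parent, length = blen, tip_pop = tip_pop,
       node_time = node_time,
       root = if (n > 1) 2L * n - 1L else 1L)
}

sim_genealogy_slow <- function(sample_sizes, scen, size_changes = NULL) {
  pops <- scen$populations
  k <- sample_sizes[pops]; k[is.na(k)] <- 0L
  n <- sum(k)
  if (n < 1) stop("no samples")
  max_k <- 4 * max(scen$ne)
  if (any(k > max_k))
    stop("parameter error: sample size exceeds 2*Ne limit")
  parent <- integer(2 * n - 1); blen <- numeric(2 * n - 1)
  node_time <- numeric(2 * n - 1)
  tip_pop <- rep(pops, times = k)
  # active lineages per population
  act <- split(seq_len(n), factor(tip_pop, levels = pops))
  ne_now <- scen$ne
  sc <- if (is.null(size_changes)) {
    data.frame(time = numeric(0), pop = character(0), ne = numeric(0))
  } else as.data.frame(size_changes)
  agenda <- rbind(
    if (nrow(scen$events))
      data.frame(time = scen$events$time, type = "split",
                 a = scen$events$derived, b = scen$events$source,
                 ne = NA_real_) else NULL,
    if (nrow(sc)) data.frame(time = sc$time, type = "resize", a = sc$pop,
                             b = NA_character_, ne = sc$ne) else NULL)
  if (!is.null(agenda)) agenda <- agenda[order(agenda$time), , drop = FALSE]
  t_now <- 0
  next_node <- n + 1L
  ev <- 1L
  n_agenda <- if (is.null(agenda)) 0L else nrow(agenda)
  while (sum(lengths(act)) > 1) {
    t_next <- if (ev <= n_agenda) agenda$time[ev] else Inf
    # coalesce within the current epoch
    repeat {
      ks <- lengths(act)
      rates <- ifelse(ks >= 2, ks * (ks - 1) / 2 / (2 * ne_now), 0)
      tot <- sum(rates)
      if (tot > 0) {
        w <- rexp(1, tot)
      } else {
        if (is.infinite(t_next))
          stop("internal error: uncoalesced lineages with no pending events")
        w <- Inf
      }
      if (t_now + w >= t_next) { t_now <- t_next; break }
      t_now <- t_now + w
      p <- sample.int(length(pops), 1, prob = rates)
      pair <- if (length(act[[p]]) == 2) act[[p]] else sample(act[[p]], 2)
      node <- next_node; next_node <- next_node + 1L
      node_time[node] <- t_now
      parent[pair] <- node
      blen[pair] <- t_now - node_time[pair]
      act[[p]] <- c(setdiff(act[[p]], pair), node)
      if (next_node > 2L * n - 1L) break
    }
    if (next_node > 2L * n - 1L) break
    if (ev <= n_agenda && t_now >= agenda$time[ev]) {
      if (agenda$type[ev] == "split") {
        ia <- match(agenda$a[ev], pops); ib <- match(agenda$b[ev], pops)
        act[[ib]] <- c(act[[ib]], act[[ia]]); act[[ia]] <- integer(0)
      } else {
        ne_now[match(agenda$a[ev], pops)] <- agenda$ne[ev]
      }
      ev <- ev + 1L
    }
  }
  list(n_tips = n, parent = parent, length = blen, tip_pop = tip_pop,
       node_time = node_time,
       root = if (n > 1) 2L * n - 1L else 1L)
}

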