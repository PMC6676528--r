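# Monte-Carlo realisation of the branching process.  Two code paths share the
# same generative model: simulate_schedule()/simulate_scenario() build an
# explicit gene-tree node table for a single seeded realisation (inspection,
# Newick export, pair enumeration for the similarity generator), while
# simulate_pair_counts() runs many replicates at once as a flat forest with
# vectorised per-generation survivor draws and a vectorised backward pass.

draw_survivors <- function(d, n) {
  if (n == 0L) return(integer(0))
  sample.int(d$r + 1L, n, replace = TRUE, prob = d$u) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed))
    stop_wgdfrac("`seed` must be a single integer")
}

#' Simulate a gene tree under an event schedule
#'
#' Realises the branching process: each of the `M1` generation-1 genes is
#' replaced at every WGD by `r` copies of which `k` survive, with `k`
#' drawn from the event's survival vector.  Which of the `r` positional
#' copies survive is immaterial to pair counting by most recent common
#' ancestor, so survivors are not position-labelled, and dead subtrees
#' are never materialised.
#'
#' @param schedule A [event_schedule()].
#' @param seed Integer random seed (mandatory; identical seeds give
#'   identical trees).
#' @return A `wgd_gene_tree`: a tibble with one row per node
#'   (`node_id`, `generation`, `parent_id`, `time_My`, `genome`,
#'   `is_leaf`), with the generating object attached as attribute
#'   `"source"`.
#' @examples
#' simulate_schedule(event_schedule(2, wgd_event(10, c(0, 0.5, 0.5))), seed = 1)
#' @export
simulate_schedule <- function(schedule, seed) {
  check_schedule(schedule)
  check_seed(seed)
  set.seed(seed)
  survs <- wgd_survivals(schedule)
  times <- schedule$events$time
  acc <- new_tree_acc()
  frontier <- acc$add(n = schedule$M1, parent = rep(NA_integer_, schedule$M1),
                      generation = 1L, time = times[1], genome = NA_character_)
  for (i in seq_along(survs)) {
    k <- draw_survivors(survs[[i]], length(frontier))
    frontier <- acc$add(parent = frontier[rep.int(seq_along(frontier), k)],
                        generation = i + 1L, time = times[i + 1L],
                        genome = NA_character_)
  }
  acc$leaves(frontier)
  finish_tree(acc, source = schedule, kind = "schedule")
}

#' Simulate a gene tree under a speciation scenario
#'
#' The pre-speciation process is shared; at speciation each surviving
#' gene is copied into genomes A and B, the speciation survival vector
#' deciding whether both copies, exactly one (its genome chosen
#' uniformly), or neither persist.  Thereafter the two genomes evolve
#' independently under their own WGD lists until each is observed.
#'
#' @param scenario A [speciation_scenario()].
#' @inheritParams simulate_schedule
#' @return A `wgd_gene_tree` whose post-speciation nodes carry a
#'   `genome` label `"A"` or `"B"`.
#' @export
simulate_scenario <- function(scenario, seed) {
  check_scenario(scenario)
  check_seed(seed)
  set.seed(seed)
  survs <- scenario_shared_wgds(scenario)
  times <- scenario$shared$time
  acc <- new_tree_acc()
  frontier <- acc$add(n = scenario$M1, parent = rep(NA_integer_, scenario$M1),
                      generation = 1L, time = times[1], genome = NA_character_)
  for (i in seq_along(survs)) {
    k <- draw_survivors(survs[[i]], length(frontier))
    frontier <- acc$add(parent = frontier[rep.int(seq_along(frontier), k)],
                        generation = i + 1L, time = times[i + 1L],
                        genome = NA_character_)
  }
  s_gen <- length(survs) + 1L                    # speciation generation
  k <- draw_survivors(speciation_survival(scenario), length(frontier))
  parent <- frontier[rep.int(seq_along(frontier), k)]
  genome <- character(length(parent))
  reps <- rep.int(k, k)                          # per-child: sibling count
  genome[reps == 2L] <- rep(c("A", "B"), sum(k == 2L))
  genome[reps == 1L] <- sample(c("A", "B"), sum(k == 1L), replace = TRUE)
  for (g in c("A", "B")) {
    btbl <- if (g == "A") scenario$branch_a else scenario$branch_b
    bsurvs <- scenario_branch_wgds(btbl)
    btimes <- btbl$time
    bf <- acc$add(parent = parent[genome == g], generation = s_gen + 1L,
                  time = btimes[1], genome = g)
    for (bi in seq_along(bsurvs)) {
      kb <- draw_survivors(bsurvs[[bi]], length(bf))
      bf <- acc$add(parent = bf[rep.int(seq_along(bf), kb)],
                    generation = s_gen + 1L + bi, time = btimes[bi + 1L],
                    genome = g)
    }
    acc$leaves(bf)
  }
  finish_tree(acc, source = scenario, kind = "scenario")
}

# growing node store; add() returns the global ids of the nodes it created
new_tree_acc <- function() {
  e <- new.env(parent = emptyenv())
  e$parent <- integer(0); e$generation <- integer(0); e$time <- numeric(0)
  e$genome <- character(0); e$leaf_ids <- integer(0)
  add <- function(parent, generation, time, genome, n = length(parent)) {
    ids <- length(e$parent) + seq_len(n)
    e$parent <- c(e$parent, as.integer(parent))
    e$generation <- c(e$generation, rep(as.integer(generation), n))
    e$time <- c(e$time, rep(as.numeric(time), n))
    e$genome <- c(e$genome, rep_len(as.character(genome), n))
    ids
  }
  leaves <- function(ids) e$leaf_ids <- c(e$leaf_ids, ids)
  list(add = add, leaves = leaves, env = e)
}

finish_tree <- function(acc, source, kind) {
  e <- acc$env
  tbl <- tibble::tibble(
    node_id = seq_along(e$parent),
    generation = e$generation,
    parent_id = e$parent,
    time_My = e$time,
    genome = e$genome,
    is_leaf = seq_along(e$parent) %in% e$leaf_ids
  )
  structure(tbl, class = c("wgd_gene_tree", class(tbl)),
            source = source, tree_kind = kind)
}

#' @export
print.wgd_gene_tree <- function(x, ...) {
  cat(sprintf("<wgd_gene_tree> (%s) %d nodes, %d observed leaves\n",
              attr(x, "tree_kind"), nrow(x), sum(x$is_leaf)))
  NextMethod()
}

#' Count observed gene pairs by event of origin
#'
#' Groups the pairs of observed genes of a simulated tree by the
#' generation of their most recent common ancestor.  For single-genome
#' trees these are paralog i-pairs plus the count of unpaired genes
#' (observed genes whose root lineage left no partner); for speciation
#' scenarios they are ortholog pairs, i.e. pairs with one leaf in each
#' genome, grouped by MRCA generation (shared WGDs and the speciation
#' itself).
#'
#' @param tree A `wgd_gene_tree` from [simulate_schedule()] or
#'   [simulate_scenario()].
#' @return A `wgd_pair_counts` tibble of integer counts; see
#'   [expected_paralog_pairs()] for the shape.
#' @export
count_pairs <- function(tree) {
  if (!inherits(tree, "wgd_gene_tree"))
    stop_wgdfrac("`tree` must be a wgd_gene_tree")
  src <- attr(tree, "source")
  scenario <- identical(attr(tree, "tree_kind"), "scenario")
  n_nodes <- nrow(tree)
  if (scenario) {
    nA <- as.numeric(tree$is_leaf & tree$genome %in% "A")
    nB <- as.numeric(tree$is_leaf & tree$genome %in% "B")
    for (g in sort(unique(tree$generation), decreasing = TRUE)) {
      ids <- which(tree$generation == g & !is.na(tree$parent_id))
      if (!length(ids)) next
      par <- tree$parent_id[ids]
      rs <- rowsum(cbind(nA[ids], nB[ids]), par)
      idx <- as.integer(rownames(rs))
      nA[idx] <- nA[idx] + rs[, 1]
      nB[idx] <- nB[idx] + rs[, 2]
    }
    # cross pairs with MRCA exactly v: nA_v * nB_v - sum over children of nA_c * nB_c
    child_prod <- numeric(n_nodes)
    inner <- which(!is.na(tree$parent_id))
    if (length(inner)) {
      rs <- rowsum(nA[inner] * nB[inner], tree$parent_id[inner])
      child_prod[as.integer(rownames(rs))] <- rs[, 1]
    }
    mrca_pairs <- nA * nB - child_prod
    s_gen <- sum(src$shared$kind == "wgd") + 1L
    counts <- vapply(seq_len(s_gen), function(i)
      sum(mrca_pairs[tree$generation == i]), numeric(1))
    tbl <- tibble::tibble(origin_event = seq_len(s_gen),
                          time_My = src$shared$time,
                          kind = "ortholog",
                          expected_pairs = as.integer(round(counts)))
    roots <- which(is.na(tree$parent_id))
    unp <- sum(nA[roots] * (nB[roots] == 0) + nB[roots] * (nA[roots] == 0))
    return(new_pair_counts(tbl, unpaired = unp,
                           total_genes = sum(tree$is_leaf), simulated = TRUE))
  }
  n <- as.numeric(tree$is_leaf)
  sq <- numeric(n_nodes)
  for (g in sort(unique(tree$generation), decreasing = TRUE)) {
    ids <- which(tree$generation == g & !is.na(tree$parent_id))
    if (!length(ids)) next
    par <- tree$parent_id[ids]
    rs <- rowsum(cbind(n[ids], n[ids]^2), par)
    idx <- as.integer(rownames(rs))
    n[idx] <- rs[, 1]
    sq[idx] <- rs[, 2]
  }
  mrca_pairs <- (n^2 - sq) / 2
  K <- n_wgd(src)
  counts <- vapply(seq_len(K), function(i)
    sum(mrca_pairs[tree$generation == i]), numeric(1))
  roots <- which(is.na(tree$parent_id))
  tbl <- tibble::tibble(origin_event = seq_len(K),
                        time_My = src$events$time[src$events$kind == "wgd"],
                        kind = "paralog",
                        expected_pairs = as.integer(round(counts)))
  new_pair_counts(tbl, unpaired = sum(n[roots] == 1),
                  total_genes = sum(tree$is_leaf), simulated = TRUE)
}

#' Enumerate observed gene pairs with their event of origin
#'
#' Lists every observed pair of a simulated tree with the generation of
#' its most recent common ancestor — paralog pairs for single-genome
#' trees, cross-genome ortholog pairs for scenarios (within-genome
#' pairs of a scenario are not listed; the observed comparison between
#' two species sees only cross-genome pairs).
#'
#' @param tree A `wgd_gene_tree`.
#' @return A tibble with columns `gene_1`, `gene_2` (leaf node ids),
#'   `origin_event`, `genome_1`, `genome_2`.
#' @export
enumerate_pairs <- function(tree) {
  if (!inherits(tree, "wgd_gene_tree"))
    stop_wgdfrac("`tree` must be a wgd_gene_tree")
  scenario <- identical(attr(tree, "tree_kind"), "scenario")
  src <- attr(tree, "source")
  max_origin <- if (scenario) sum(src$shared$kind == "wgd") + 1L else n_wgd(src)
  leafsets <- vector("list", nrow(tree))
  leafsets[tree$is_leaf] <- as.list(tree$node_id[tree$is_leaf])
  out <- list()
  for (g in sort(unique(tree$generation), decreasing = TRUE)) {
    ids <- which(tree$generation == g & !is.na(tree$parent_id))
    ids <- ids[!vapply(leafsets[ids], is.null, logical(1))]
    if (!length(ids)) next
    by_parent <- split(ids, tree$parent_id[ids])
    for (p in seq_along(by_parent)) {
      ch <- by_parent[[p]]
      pid <- tree$parent_id[ch[1]]
      if (length(ch) >= 2L && tree$generation[pid] <= max_origin) {
        for (a in seq_len(length(ch) - 1L)) for (b in (a + 1L):length(ch)) {
          la <- leafsets[[ch[a]]]; lb <- leafsets[[ch[b]]]
          prs <- cbind(rep(la, each = length(lb)), rep(lb, length(la)))
          out[[length(out) + 1L]] <- cbind(prs, tree$generation[pid])
        }
      }
      leafsets[[pid]] <- unlist(leafsets[ch], use.names = FALSE)
    }
  }
  if (!length(out)) {
    res <- tibble::tibble(gene_1 = integer(0), gene_2 = integer(0),
                          origin_event = integer(0),
                          genome_1 = character(0), genome_2 = character(0))
    return(res)
  }
  m <- do.call(rbind, out)
  res <- tibble::tibble(gene_1 = m[, 1], gene_2 = m[, 2], origin_event = m[, 3],
                        genome_1 = tree$genome[m[, 1]], genome_2 = tree$genome[m[, 2]])
  if (scenario)
    res <- dplyr::filter(res, .data$genome_1 != .data$genome_2)
  dplyr::arrange(res, .data$origin_event, .data$gene_1, .data$gene_2)
}

#' Replicated pair counts by Monte-Carlo simulation
#'
#' Runs many independent realisations of a schedule or scenario as one
#' vectorised forest and returns per-replicate pair counts by event of
#' origin — the work-horse behind simulator-versus-closed-form checks.
#'
#' @param x A [event_schedule()] or [speciation_scenario()].
#' @param n_rep Number of replicates.
#' @param seed Integer random seed.
#' @return A tibble in long form: `replicate`, `origin_event`, `pairs`.
#'   A per-replicate gene summary (`replicate`, `total_genes`,
#'   `unpaired` — the latter `NA` for scenarios) is attached as
#'   attribute `"genes"`.
#' @examples
#' sims <- simulate_pair_counts(
#'   event_schedule(1, wgd_event(10, c(0, 0.6, 0.4)), wgd_event(5, c(0, 0.6, 0.4))),
#'   n_rep = 1000, seed = 7)
#' dplyr::summarise(dplyr::group_by(sims, origin_event), mean = mean(pairs))
#' @export
simulate_pair_counts <- function(x, n_rep, seed) {
  check_seed(seed)
  if (n_rep < 1) stop_wgdfrac("`n_rep` must be >= 1")
  set.seed(seed)
  if (inherits(x, "wgd_schedule")) {
    eng <- forest_engine(x$M1, wgd_survivals(x), n_rep, scenario_sp = NULL)
    K <- n_wgd(x)
    genes <- tibble::tibble(replicate = seq_len(n_rep),
                            total_genes = eng$total, unpaired = eng$unpaired)
  } else if (inherits(x, "wgd_scenario")) {
    eng <- forest_engine(x$M1, scenario_shared_wgds(x), n_rep,
                         scenario_sp = speciation_survival(x),
                         branch_a = scenario_branch_wgds(x$branch_a),
                         branch_b = scenario_branch_wgds(x$branch_b))
    K <- sum(x$shared$kind == "wgd") + 1L
    genes <- tibble::tibble(replicate = seq_len(n_rep),
                            total_genes = eng$total, unpaired = eng$unpaired)
  } else stop_wgdfrac("`x` must be a wgd_schedule or wgd_scenario")
  out <- tibble::tibble(
    replicate = rep(seq_len(n_rep), K),
    origin_event = rep(seq_len(K), each = n_rep),
    pairs = as.vector(eng$pairs)
  )
  structure(out, genes = genes)
}

# vectorised multi-replicate forest.  Returns pairs (n_rep x K matrix),
# total (observed genes per replicate), unpaired (per replicate; schedule only).
forest_engine <- function(M1, survs, n_rep, scenario_sp = NULL,
                          branch_a = NULL, branch_b = NULL) {
  n0 <- as.integer(M1 * n_rep)
  K_shared <- length(survs)
  parents <- vector("list", K_shared)
  repids <- vector("list", K_shared + 1L)
  pops <- integer(K_shared + 1L)
  repids[[1]] <- rep(seq_len(n_rep), each = M1)
  pops[1] <- n0
  cur_n <- n0
  for (i in seq_len(K_shared)) {
    k <- draw_survivors(survs[[i]], cur_n)
    parents[[i]] <- rep.int(seq_len(cur_n), k)
    repids[[i + 1L]] <- repids[[i]][parents[[i]]]
    cur_n <- length(parents[[i]])
    pops[i + 1L] <- cur_n
  }

  agg <- function(vals, group, n_out) {
    out <- numeric(n_out)
    if (length(group)) {
      rs <- rowsum(vals, group)
      out[as.integer(rownames(rs))] <- rs
    }
    out
  }

  if (is.null(scenario_sp)) {
    K <- K_shared
    n <- rep(1, cur_n)
    P <- matrix(0, n_rep, max(K, 1L))
    for (i in rev(seq_len(K))) {
      par <- parents[[i]]
      S1 <- agg(n, par, pops[i])
      S2 <- agg(n^2, par, pops[i])
      pv <- (S1^2 - S2) / 2
      if (pops[i]) {
        rp <- rowsum(pv, repids[[i]])
        P[as.integer(rownames(rp)), i] <- rp
      }
      n <- S1
    }
    total <- agg(n, repids[[1]], n_rep)
    unpaired <- agg(as.numeric(n == 1), repids[[1]], n_rep)
    return(list(pairs = P[, seq_len(K), drop = FALSE], total = total,
                unpaired = unpaired))
  }

  # speciation: cur_n genes at generation s = K_shared + 1
  k <- draw_survivors(scenario_sp, cur_n)
  sp_parent <- rep.int(seq_len(cur_n), k)
  sibs <- rep.int(k, k)
  genome <- character(length(sp_parent))
  genome[sibs == 2L] <- rep(c("A", "B"), sum(k == 2L))
  genome[sibs == 1L] <- sample(c("A", "B"), sum(k == 1L), replace = TRUE)

  # descendant leaf counts of each speciation child, per branch
  branch_desc <- function(sel_parent, bsurvs) {
    m <- length(sel_parent)
    bparents <- vector("list", length(bsurvs))
    bpops <- integer(length(bsurvs) + 1L)
    bpops[1] <- m
    cn <- m
    for (bi in seq_along(bsurvs)) {
      kb <- draw_survivors(bsurvs[[bi]], cn)
      bparents[[bi]] <- rep.int(seq_len(cn), kb)
      cn <- length(bparents[[bi]])
      bpops[bi + 1L] <- cn
    }
    n <- rep(1, cn)
    for (bi in rev(seq_along(bsurvs))) n <- agg(n, bparents[[bi]], bpops[bi])
    n
  }
  idxA <- which(genome == "A"); idxB <- which(genome == "B")
  descA_child <- branch_desc(sp_parent[idxA], branch_a)
  descB_child <- branch_desc(sp_parent[idxB], branch_b)
  # per generation-s gene: descendants in each genome
  nA <- agg(descA_child, sp_parent[idxA], cur_n)
  nB <- agg(descB_child, sp_parent[idxB], cur_n)

  s_gen <- K_shared + 1L
  P <- matrix(0, n_rep, s_gen)
  # s-origin: cross pairs between the two copies of the same gene
  pv <- nA * nB
  if (cur_n) {
    rp <- rowsum(pv, repids[[s_gen]])
    P[as.integer(rownames(rp)), s_gen] <- rp
  }
  for (i in rev(seq_len(K_shared))) {
    par <- parents[[i]]
    SA <- agg(nA, par, pops[i])
    SB <- agg(nB, par, pops[i])
    Sprod <- agg(nA * nB, par, pops[i])
    pv <- SA * SB - Sprod
    if (pops[i]) {
      rp <- rowsum(pv, repids[[i]])
      P[as.integer(rownames(rp)), i] <- rp
    }
    nA <- SA; nB <- SB
  }
  total <- agg(nA + nB, repids[[1]], n_rep)
  # ortholog-unpaired: observed genes of a root whose other genome kept nothing
  unp <- nA * (nB == 0) + nB * (nA == 0)
  list(pairs = P, total = total, unpaired = agg(unp, repids[[1]], n_rep))
}

#' Export a simulated gene tree as Newick text
#'
#' One Newick string per root lineage; leaf labels are
#' `genome:gene<node_id>` (genome prefix only for scenario trees) and
#' branch lengths are the inter-event intervals in My.
#'
#' @param tree A `wgd_gene_tree`.
#' @param path Optional file to write to (one tree per line).
#' @return Character vector of Newick strings, invisibly if `path` is
#'   given.
#' @export
tree_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "wgd_gene_tree"))
    stop_wgdfrac("`tree` must be a wgd_gene_tree")
  kids <- split(tree$node_id[!is.na(tree$parent_id)],
                tree$parent_id[!is.na(tree$parent_id)])
  lab <- ifelse(is.na(tree$genome), paste0("gene", tree$node_id),
                paste0(tree$genome, ":gene", tree$node_id))
  rec <- function(id) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || !length(ch)) return(lab[id])
    paste0("(", paste(vapply(ch, function(c) {
      bl <- tree$time_My[id] - tree$time_My[c]
      paste0(rec(c), ":", format(bl, digits = 10))
    }, character(1)), collapse = ","), ")")
  }
  roots <- tree$node_id[is.na(tree$parent_id)]
  # drop roots with no observed descendants entirely? keep them as bare leaves
  nwk <- vapply(roots, function(r) paste0(rec(r), ";"), character(1))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
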