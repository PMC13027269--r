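# Group-aware partitioning. Samples from the same acquisition group
# (plot x session) always land in the same partition and the same CV fold,
# so spatially/temporally correlated images never straddle train and test.

#' Grouped train/validation/test split
#'
#' Greedy group-level allocation targeting the requested sample-count
#' ratios: groups are processed in seeded random order and each goes to
#' the partition with the largest remaining sample deficit, so the
#' realized fractions deviate from the targets by at most one group size
#' (exactly zero for equal-sized groups under exactly divisible ratios).
#' The random order also spreads structurally similar groups — e.g.
#' single-class plots — across partitions instead of funnelling the
#' largest ones into training.
#'
#' @param groups character/factor vector of group ids, one per sample.
#' @param ratios target (train, val, test) sample fractions summing to 1.
#' @param seed integer seed; the plan is deterministic given
#'   `(groups, ratios, seed)`.
#' @return an object of class `"split_plan"`: `partition` (per-sample
#'   factor), `group_partition` (named vector) and the realized fractions.
#' @export
make_split <- function(groups, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8, all(ratios > 0))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 3) {
    stop("make_split(): need at least 3 groups to honor all partitions",
         call. = FALSE)
  }
  set.seed(seed)
  ord <- sample(names(sizes))
  parts <- c("train", "val", "test")
  target <- ratios * length(groups)
  assigned <- c(train = 0, val = 0, test = 0)
  gpart <- character(length(sizes)); names(gpart) <- ord
  for (g in ord) {
    deficit <- target - assigned
    gpart[g] <- parts[which.max(deficit)]
    assigned[gpart[g]] <- assigned[gpart[g]] + sizes[[g]]
  }
  # guarantee every partition holds at least one group
  for (pt in c("val", "test")) {
    if (!any(gpart == pt)) {
      donor_part <- names(which.max(table(factor(gpart, levels = parts))))
      donors <- names(gpart)[gpart == donor_part]
      mv <- donors[which.min(sizes[donors])]
      gpart[mv] <- pt
      assigned[donor_part] <- assigned[donor_part] - sizes[[mv]]
      assigned[pt] <- assigned[pt] + sizes[[mv]]
    }
  }
  partition <- factor(gpart[groups], levels = parts)
  structure(list(partition = partition,
                 group_partition = gpart,
                 ratios = ratios,
                 realized = as.vector(assigned / length(groups)),
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Grouped split plan\n")
  tab <- table(x$partition)
  for (p in names(tab)) {
    cat(sprintf("  %-5s %5d samples (%.1f%%), %d groups\n", p, tab[[p]],
                100 * tab[[p]] / length(x$partition),
                sum(x$group_partition == p)))
  }
  invisible(x)
}

#' Grouped k-fold assignment on the training partition
#'
#' Groups of the training partition are allocated greedily (largest first,
#' seeded ties) to the currently smallest fold; folds are disjoint and
#' exhaust the training partition.
#'
#' @param split a [make_split()] plan.
#' @param groups the same per-sample group vector the plan was built from.
#' @param k number of folds.
#' @param seed integer seed.
#' @return a list: `fold` (per-sample integer, `NA` outside training),
#'   `group_fold` (named vector over training groups).
#' @export
make_folds <- function(split, groups, k = 5L, seed = 1L) {
  groups <- as.character(groups)
  tr_groups <- names(split$group_partition)[split$group_partition == "train"]
  if (length(tr_groups) < k) {
    stop(sprintf("make_folds(): %d training groups < k = %d folds",
                 length(tr_groups), k), call. = FALSE)
  }
  sizes <- table(groups[groups %in% tr_groups])
  set.seed(seed)
  ord <- sample(names(sizes))
  ord <- ord[order(-as.integer(sizes[ord]))]
  load <- numeric(k)
  gfold <- integer(length(ord)); names(gfold) <- ord
  for (g in ord) {
    f <- which.min(load)
    gfold[g] <- f
    load[f] <- load[f] + sizes[[g]]
  }
  fold <- rep(NA_integer_, length(groups))
  intr <- groups %in% tr_groups
  fold[intr] <- gfold[groups[intr]]
  list(fold = fold, group_fold = gfold, k = as.integer(k))
}
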