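# Domain types: ranking observations, datasets, partitions, worth states,
# and readers/writers for the two supported CSV layouts.

#' Construct a single ranking observation
#'
#' One judge's ordinal preference: an ordered prefix of most-preferred objects
#' (`ranked`, best first) together with the set of objects the judge considered
#' when forming the ranking. A *partial* ranking has fewer ranked objects than
#' considered objects; an *incomplete* ranking considers only a subset of all
#' objects; a pairwise comparison is an incomplete ranking of two objects with
#' one ranked.
#'
#' @param ranked Integer vector of object indices, most-preferred first.
#' @param considered Integer vector of object indices the judge considered.
#'   Stored sorted; must contain every ranked object and have length >= 2.
#' @return An object of class `"rcbtl_obs"`.
#' @export
ranking_observation <- function(ranked, considered) {
  ranked <- as.integer(ranked)
  considered <- sort(unique(as.integer(considered)))
  if (length(ranked) < 1L) stop("at least one object must be ranked")
  if (anyDuplicated(ranked)) stop("ranked objects contain duplicates")
  if (length(considered) < 2L) stop("at least two objects must be considered")
  if (!all(ranked %in% considered)) {
    stop("every ranked object must belong to the considered set")
  }
  structure(list(ranked = ranked, considered = considered), class = "rcbtl_obs")
}

#' Construct a ranking dataset
#'
#' Bundles `I` ranking observations over a common universe of `n_objects`
#' objects. An empty observation list is permitted so that prior (no-data)
#' simulation has a natural container; the CSV readers always require at
#' least one row.
#'
#' @param observations List of [ranking_observation()] objects.
#' @param n_objects Number of objects `J` in the universe.
#' @param labels Optional character vector of object names (length `J`).
#' @return An object of class `"rcbtl_data"`.
#' @export
ranking_dataset <- function(observations, n_objects, labels = NULL) {
  n_objects <- as.integer(n_objects)
  stopifnot(n_objects >= 1L)
  if (is.null(labels)) labels <- paste0("object_", seq_len(n_objects))
  if (length(labels) != n_objects) stop("labels must have length n_objects")
  for (i in seq_along(observations)) {
    o <- observations[[i]]
    if (!inherits(o, "rcbtl_obs")) stop("observation ", i, " is not an rcbtl_obs")
    if (any(o$considered < 1L) || any(o$considered > n_objects)) {
      stop("observation ", i, " references objects outside 1..", n_objects)
    }
  }
  structure(
    list(observations = observations, n_objects = n_objects, labels = labels),
    class = "rcbtl_data"
  )
}

#' @export
print.rcbtl_data <- function(x, ...) {
  I <- length(x$observations)
  cat("Ranking dataset:", I, "observation(s) of", x$n_objects, "objects\n")
  if (I > 0L) {
    R <- vapply(x$observations, function(o) length(o$ranked), integer(1))
    S <- vapply(x$observations, function(o) length(o$considered), integer(1))
    cat("  ranked lengths:", paste(range(R), collapse = "-"),
        "| considered sizes:", paste(range(S), collapse = "-"), "\n")
  }
  invisible(x)
}

#' Read ranking data from CSV
#'
#' Expected layout: an optional `judge` column, columns `rank_1`, ...,
#' `rank_M` holding object names in preference order (blank cells may trail a
#' prefix, giving a partial ranking), and an optional `considered` column
#' holding a semicolon-separated set of object names. When `considered` is
#' absent or blank, the judge is assumed to have considered all objects.
#'
#' @param path Path to a UTF-8 comma-separated file.
#' @param objects Optional character vector fixing the object universe and its
#'   index order. By default the universe is every name appearing in the file,
#'   in order of first appearance.
#' @param considered_sep Delimiter inside the `considered` column.
#' @return An [ranking_dataset()] with names mapped to integer indices.
#' @export
read_rankings_csv <- function(path, objects = NULL, considered_sep = ";") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  if (nrow(raw) == 0L) stop("no observations in ", path)
  rank_cols <- grep("^rank_[0-9]+$", names(raw), value = TRUE)
  if (length(rank_cols) == 0L) stop("no rank_1..rank_M columns found in ", path)
  rank_cols <- rank_cols[order(as.integer(sub("^rank_", "", rank_cols)))]
  has_considered <- "considered" %in% names(raw)

  ranked_names <- lapply(seq_len(nrow(raw)), function(i) {
    cells <- trimws(unlist(raw[i, rank_cols], use.names = FALSE))
    nonblank <- which(!is.na(cells) & nzchar(cells))
    if (length(nonblank) == 0L) stop("row ", i, ": no ranked objects")
    if (!identical(nonblank, seq_len(max(nonblank)))) {
      stop("row ", i, ": blank rank cells may only trail the ranked prefix")
    }
    cells[nonblank]
  })
  considered_names <- lapply(seq_len(nrow(raw)), function(i) {
    if (!has_considered) return(NULL)
    cell <- trimws(raw$considered[i])
    if (is.na(cell) || !nzchar(cell)) return(NULL)
    trimws(strsplit(cell, considered_sep, fixed = TRUE)[[1]])
  })

  seen <- unique(c(unlist(ranked_names), unlist(considered_names)))
  if (is.null(objects)) {
    objects <- seen
  } else if (!all(seen %in% objects)) {
    stop("unknown object name(s): ",
         paste(setdiff(seen, objects), collapse = ", "))
  }
  J <- length(objects)

  observations <- lapply(seq_len(nrow(raw)), function(i) {
    r <- ranked_names[[i]]
    if (anyDuplicated(r)) {
      stop("row ", i, ": duplicate object '", r[duplicated(r)][1], "' in ranking")
    }
    cons <- considered_names[[i]]
    if (is.null(cons)) {
      cons_idx <- seq_len(J)
    } else {
      cons_idx <- match(cons, objects)
      if (!all(r %in% cons)) {
        stop("row ", i, ": ranked object outside the considered set")
      }
    }
    ranking_observation(match(r, objects), cons_idx)
  })
  ranking_dataset(observations, J, labels = objects)
}

#' Write ranking data to CSV
#'
#' Inverse of [read_rankings_csv()]: one row per judge with the ranked prefix
#' in `rank_1..rank_M` (M = longest prefix in the data) and the considered set
#' as a semicolon-separated `considered` column.
#'
#' @param data An [ranking_dataset()].
#' @param path Output file path.
#' @param considered_sep Delimiter for the considered set.
#' @return `path`, invisibly.
#' @export
write_rankings_csv <- function(data, path, considered_sep = ";") {
  obs <- data$observations
  if (length(obs) == 0L) stop("dataset has no observations to write")
  M <- max(vapply(obs, function(o) length(o$ranked), integer(1)))
  rows <- lapply(seq_along(obs), function(i) {
    r <- data$labels[obs[[i]]$ranked]
    c(judge = as.character(i),
      stats::setNames(c(r, rep("", M - length(r))), paste0("rank_", seq_len(M))),
      considered = paste(data$labels[obs[[i]]$considered],
                         collapse = considered_sep))
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pairwise comparison data from CSV
#'
#' Expected layout: columns `winner,loser` of object names; each row becomes
#' an incomplete ranking of the two objects with the winner ranked first.
#'
#' @inheritParams read_rankings_csv
#' @return An [ranking_dataset()].
#' @export
read_pairwise_csv <- function(path, objects = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  if (nrow(raw) == 0L) stop("no observations in ", path)
  if (!all(c("winner", "loser") %in% names(raw))) {
    stop("expected columns 'winner' and 'loser' in ", path)
  }
  seen <- unique(c(rbind(raw$winner, raw$loser)))
  if (is.null(objects)) {
    objects <- seen
  } else if (!all(seen %in% objects)) {
    stop("unknown object name(s): ",
         paste(setdiff(seen, objects), collapse = ", "))
  }
  observations <- lapply(seq_len(nrow(raw)), function(i) {
    if (raw$winner[i] == raw$loser[i]) {
      stop("row ", i, ": winner and loser are the same object")
    }
    ranking_observation(match(raw$winner[i], objects),
                        match(c(raw$winner[i], raw$loser[i]), objects))
  })
  ranking_dataset(observations, length(objects), labels = objects)
}

#' Construct a partition of objects into clusters
#'
#' @param assignment Integer vector; `assignment[j]` is the cluster label of
#'   object `j`. Labels must be `1..K` with every cluster nonempty. The
#'   labelling need not be canonical; see [canonicalize()].
#' @return An object of class `"rcbtl_partition"` with elements `assignment`,
#'   `K` (number of clusters), and `sizes` (cluster sizes).
#' @export
partition <- function(assignment) {
  assignment <- as.integer(assignment)
  J <- length(assignment)
  if (J < 1L) stop("partition of an empty object set")
  K <- max(assignment)
  sizes <- tabulate(assignment, nbins = K)
  if (min(assignment) < 1L || any(sizes == 0L)) {
    stop("cluster labels must be 1..K with all clusters nonempty")
  }
  structure(list(assignment = assignment, K = K, sizes = sizes),
            class = "rcbtl_partition")
}

#' @export
print.rcbtl_partition <- function(x, ...) {
  groups <- split(seq_along(x$assignment), x$assignment)
  cat("Partition of", length(x$assignment), "objects into", x$K, "cluster(s):",
      paste(vapply(groups, function(g) paste0("{", paste(g, collapse = ","), "}"),
                   character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Canonicalize a partition's cluster labels
#'
#' Relabels clusters in ascending order of their smallest member, so equal
#' partitions compare equal regardless of incoming labels. Idempotent.
#'
#' @param p An [partition()].
#' @return The canonically labelled partition.
#' @export
canonicalize <- function(p) {
  partition(match(p$assignment, unique(p$assignment)))
}

#' Enumerate all partitions of J objects
#'
#' Generates every set partition of `{1..J}` in canonical labelling via
#' restricted-growth strings. Intended as an exact small-`J` tool (prior
#' normalisation, test oracles); the count is the Bell number, so `J` is
#' capped at 10.
#'
#' @param J Number of objects, `1 <= J <= 10`.
#' @return A list of [partition()] objects.
#' @export
enumerate_partitions <- function(J) {
  J <- as.integer(J)
  if (J < 1L) stop("J must be >= 1")
  if (J > 10L) stop("enumerate_partitions() is limited to J <= 10")
  res <- list()
  rgs <- integer(J)
  recurse <- function(pos, maxk) {
    if (pos > J) {
      res[[length(res) + 1L]] <<- partition(rgs)
      return(invisible(NULL))
    }
    for (k in seq_len(maxk + 1L)) {
      rgs[pos] <<- k
      recurse(pos + 1L, max(maxk, k))
    }
  }
  recurse(1L, 0L)
  res
}

#' Construct a worth state (partition plus cluster worths)
#'
#' Pairs a partition with one strictly positive worth per cluster and its
#' expansion to a length-`J` vector: object `j` receives the worth of its
#' cluster. Cluster worths must be pairwise distinct (they are draws from a
#' continuous slab; exact ties would silently merge clusters).
#'
#' @param partition An [partition()].
#' @param cluster_worths Numeric vector of length `K`, strictly positive and
#'   pairwise distinct; entry `k` is the shared worth of cluster `k`.
#' @return An object of class `"rcbtl_state"` with elements `partition`,
#'   `cluster_worths`, and `expanded` (the length-`J` worth vector).
#' @export
worth_state <- function(partition, cluster_worths) {
  cluster_worths <- as.numeric(cluster_worths)
  if (length(cluster_worths) != partition$K) {
    stop("need exactly one worth per cluster")
  }
  if (any(!is.finite(cluster_worths)) || any(cluster_worths <= 0)) {
    stop("cluster worths must be strictly positive and finite")
  }
  if (anyDuplicated(cluster_worths)) {
    stop("cluster worths must be pairwise distinct")
  }
  structure(
    list(partition = partition, cluster_worths = cluster_worths,
         expanded = cluster_worths[partition$assignment]),
    class = "rcbtl_state"
  )
}

#' @export
print.rcbtl_state <- function(x, ...) {
  print(x$partition)
  cat("Cluster worths:", paste(signif(x$cluster_worths, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Hyperparameters of the rank-clustered BTL model
#'
#' @param nu Positive rate of the truncated Poisson prior on the number of
#'   rank-clusters `K`.
#' @param a,b Positive shape and rate of the Gamma slab on cluster worths.
#' @return An object of class `"rcbtl_hyper"`.
#' @export
rc_hyper <- function(nu = 2, a = 1, b = 1) {
  if (any(c(nu, a, b) <= 0) || any(!is.finite(c(nu, a, b)))) {
    stop("hyperparameters must be strictly positive and finite")
  }
  structure(list(nu = nu, a = a, b = b), class = "rcbtl_hyper")
}
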