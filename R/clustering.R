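# Clustering of phenotype and mechanism-change profiles.
#
# Operational route to coarse-grained cell types and transition classes:
# similar phenotype profiles correspond to similar cells and similar
# mechanism-change profiles to similar transitions, so agglomerative
# clustering of a normalized similarity-derived distance matrix recovers
# the coarse classes. Raw BMA scores are corpus-scale dependent, so the
# distance uses a Lin-style normalization by the self-similarities.

#' Pairwise distance matrix over a profile corpus
#'
#' Propagates the corpus (unless `propagate = FALSE`), scores all profile
#' pairs with [profile_similarity()] and converts to distances
#' `d(p, q) = 1 - sim(p, q) / sqrt(sim(p, p) * sim(q, q))`, clipped to
#' [0, 1], with a zero diagonal. A profile with zero self-similarity (an
#' empty profile, or one annotated only with terms of zero information
#' content) is at distance 1 from everything but itself.
#'
#' @param profiles Corpus tibble with at least two profiles.
#' @param ontology A valid [ceq_ontology()].
#' @param ic IC table; computed from `profiles` when `NULL`.
#' @param compat Quality-compatibility table.
#' @param method `"bma"` or `"simgic"`.
#' @param mode Propagation mode.
#' @param propagate Set `FALSE` to score the asserted annotations only
#'   (used to quantify how much reasoning sharpens the similarity
#'   structure).
#' @param qualities Quality vocabulary.
#' @return A symmetric numeric matrix with profile ids as dimnames,
#'   entries in [0, 1] and zero diagonal. The underlying similarity matrix
#'   is kept in `attr(, "similarity")`.
#' @export
distance_matrix <- function(profiles, ontology, ic = NULL,
                            compat = default_compatibility(),
                            method = c("bma", "simgic"),
                            mode = c("sound", "heuristic"),
                            propagate = TRUE,
                            qualities = default_qualities()) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  profiles <- check_profile_frame(profiles)
  if (n_distinct(profiles$profile_id) < 2) {
    abort("need at least two profiles to build a distance matrix")
  }
  if (is.null(ic)) ic <- information_content(profiles, ontology, mode, qualities)
  scored <- if (propagate) {
    propagate_profiles(profiles, ontology, mode, qualities)
  } else {
    profiles
  }
  members <- split_profiles(scored)
  ids <- names(members)
  engine <- sim_engine(ic, ontology, compat)
  n <- length(ids)
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- if (method == "bma") {
        bma_score(members[[i]], members[[j]], engine)
      } else {
        simgic_score(members[[i]], members[[j]], engine, qualities)
      }
      s[i, j] <- v
      s[j, i] <- v
    }
  }
  d <- matrix(1, n, n, dimnames = list(ids, ids))
  self <- diag(s)
  ok <- self > 0
  norm <- sqrt(outer(self, self))
  d[ok, ok] <- 1 - s[ok, ok, drop = FALSE] / norm[ok, ok, drop = FALSE]
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  attr(d, "similarity") <- s
  d
}

#' Cluster profiles from a distance matrix
#'
#' Agglomerative hierarchical clustering (average linkage by default) of a
#' [distance_matrix()], cut at `k` clusters. The result is deterministic
#' for a given matrix: `stats::hclust` resolves merge ties by the order of
#' the input, which is fixed because profile ids are sorted. Labels are
#' renumbered contiguously from 1 in order of first appearance.
#'
#' @param d A square symmetric distance matrix with dimnames.
#' @param k Number of clusters, `1 <= k <= nrow(d)`.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return A `ceq_clustering` object with elements `labels` (named integer
#'   vector), `hclust` (the dendrogram), `k` and `distance` (the input
#'   matrix). Use [generics::tidy()] / [generics::glance()] to extract
#'   tibbles.
#' @export
cluster_profiles <- function(d, k, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (k < 1 || k > n) abort("`k` must be between 1 and the number of profiles")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  raw <- stats::cutree(hc, k = k)
  labels <- as.integer(factor(raw, levels = unique(raw)))
  names(labels) <- names(raw)
  structure(list(labels = labels, hclust = hc, k = as.integer(k),
                 linkage = linkage, distance = d),
            class = "ceq_clustering")
}

#' @export
print.ceq_clustering <- function(x, ...) {
  cat(sprintf("<ceq_clustering> %d profiles in %d clusters (%s linkage)\n",
              length(x$labels), x$k, x$linkage))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Tidy a profile clustering
#'
#' @param x A `ceq_clustering` from [cluster_profiles()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with columns `profile_id`, `cluster`.
#' @method tidy ceq_clustering
#' @export
tidy.ceq_clustering <- function(x, ...) {
  tibble(profile_id = names(x$labels), cluster = unname(x$labels))
}

#' @rdname tidy.ceq_clustering
#' @return `glance()`: a one-row tibble with `n`, `k`, `linkage`, the mean
#'   within- and between-cluster distances and the top merge height.
#' @method glance ceq_clustering
#' @export
glance.ceq_clustering <- function(x, ...) {
  d <- x$distance
  lab <- x$labels[rownames(d)]
  same <- outer(lab, lab, `==`)
  off <- !diag(nrow(d))
  tibble(n = length(x$labels), k = x$k, linkage = x$linkage,
         mean_within = mean(d[same & off]),
         mean_between = if (any(!same)) mean(d[!same]) else NA_real_,
         height = max(x$hclust$height))
}

#' Plot a clustered distance matrix
#'
#' Heatmap of the distance matrix with profiles ordered by the dendrogram
#' and annotated with their cluster label.
#'
#' @param object A `ceq_clustering`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ceq_clustering
#' @export
autoplot.ceq_clustering <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  df <- as_tibble(as.table(object$distance), .name_repair = ~ c("p", "q", "dist"))
  df$p <- factor(df$p, levels = ord)
  df$q <- factor(df$q, levels = ord)
  lab <- tibble(p = factor(names(object$labels), levels = ord),
                cluster = factor(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$q,
                                   fill = .data$dist)) +
    ggplot2::geom_tile() +
    ggplot2::geom_rug(data = lab, sides = "b", length = ggplot2::unit(0.02, "npc"),
                      ggplot2::aes(x = .data$p, colour = .data$cluster),
                      inherit.aes = FALSE) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance", colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot term information content
#'
#' Bar chart of per-term information content, ordered by IC.
#'
#' @param ic An IC table from [information_content()].
#' @return A ggplot object.
#' @export
plot_information_content <- function(ic) {
  df <- ic |> arrange(.data$ic_bits)
  df$term_id <- factor(df$term_id, levels = df$term_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ic_bits, y = .data$term_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "information content (bits)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Adjusted Rand index between two labelings
#'
#' Agreement between two partitions of the same profiles, corrected for
#' chance: 1 for identical partitions (up to label permutation), around 0
#' for independent ones, possibly negative for systematic disagreement.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return A scalar `<= 1`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("label vectors must have equal length")
  }
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
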