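#' Configuration of a synthetic localization study
#'
#' The generator emulates the data situation the selection strategy is
#' designed for: a small experimentally annotated training set, a larger
#' candidate pool whose non-experimental labels are the hidden true labels
#' corrupted at evidence-type-dependent rates, and a held-out test set --
#' all drawn from class-conditional Gaussian clusters in feature space.
#'
#' @param q_classes number of locations `Q` (default 4).
#' @param dim feature dimension (default 10; must be `>= q_classes`).
#' @param n_train,n_pool,n_test set sizes (defaults 60, 200, 100).
#' @param class_separation Euclidean distance scale between class centers
#'   relative to unit within-class noise (default 3).
#' @param multilabel_rate probability that a sample carries a second true
#'   location (default 0.2).
#' @param corruption named per-evidence-type probabilities that a
#'   non-experimental positive is wrong (moved to a wrong location);
#'   defaults are the complements of the confidence priors: 0.15 for
#'   "Probable", 0.20 for "Potential", 0.25 for "By similarity".
#' @param evidence_mix proportions of the three evidence types among pool
#'   labels (default equal thirds).
#' @param seed integer seed; the study is fully reproducible from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(q_classes = 4L, dim = 10L,
                             n_train = 60L, n_pool = 200L, n_test = 100L,
                             class_separation = 3,
                             multilabel_rate = 0.2,
                             corruption = c(probable = 0.15,
                                            potential = 0.20,
                                            by_similarity = 0.25),
                             evidence_mix = c(probable = 1/3,
                                              potential = 1/3,
                                              by_similarity = 1/3),
                             seed = 1L) {
  stopifnot(q_classes >= 2L, dim >= q_classes,
            n_train >= 1L, n_pool >= 1L, n_test >= 1L,
            class_separation >= 0,
            multilabel_rate >= 0, multilabel_rate <= 1)
  if (!all(nonexp_types() %in% names(corruption)))
    stop("corruption must name probable, potential and by_similarity")
  corruption <- corruption[nonexp_types()]
  stopifnot(all(corruption >= 0), all(corruption <= 1))
  evidence_mix <- evidence_mix[nonexp_types()]
  stopifnot(all(evidence_mix >= 0), sum(evidence_mix) > 0)
  evidence_mix <- evidence_mix / sum(evidence_mix)
  structure(list(q_classes = as.integer(q_classes), dim = as.integer(dim),
                 n_train = as.integer(n_train), n_pool = as.integer(n_pool),
                 n_test = as.integer(n_test),
                 class_separation = class_separation,
                 multilabel_rate = multilabel_rate,
                 corruption = corruption, evidence_mix = evidence_mix,
                 seed = as.integer(seed)),
            class = "pneaselect_synthetic_config")
}

# draw n samples: features + true signed label matrix
draw_cluster_samples <- function(n, centers, cfg) {
  Q <- cfg$q_classes
  truth <- matrix(-1L, n, Q)
  feats <- matrix(0, n, cfg$dim)
  for (i in seq_len(n)) {
    primary <- sample.int(Q, 1L)
    labs <- primary
    if (runif(1L) < cfg$multilabel_rate) {
      second <- sample(setdiff(seq_len(Q), primary), 1L)
      labs <- c(primary, second)
    }
    truth[i, labs] <- 1L
    center <- colMeans(centers[labs, , drop = FALSE])
    feats[i, ] <- center + rnorm(cfg$dim)
  }
  list(features = feats, truth = truth)
}

#' Generate a synthetic localization study
#'
#' Class centers sit at `class_separation` along orthogonal coordinate
#' axes; a sample's features are an isotropic unit-variance Gaussian around
#' the mean of its true-location centers.  Training and test labels equal
#' the truth (training statuses experimental/negative).  Each pool
#' sample's true positives are displayed as non-experimental positives of
#' a random evidence type; with that type's corruption probability the
#' positive is moved to a uniformly chosen wrong location.  Hidden truth is
#' returned in separate `truth_*` fields and never enters the pool's
#' statuses.
#'
#' @param config a [synthetic_config()].
#' @return list of class `pneaselect_synthetic_study` with `train`, `pool`,
#'   `test` ([labeled_set()]s), `truth_pool`, `truth_test` (signed
#'   matrices), `pool_correct` (logical: all non-experimental labels of the
#'   pool row match the truth), `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  Q <- cfg$q_classes
  locations <- paste0("loc", seq_len(Q))
  centers <- matrix(0, Q, cfg$dim)
  centers[cbind(seq_len(Q), seq_len(Q))] <- cfg$class_separation

  sign_to_status <- function(truth) {
    status <- matrix("negative", nrow(truth), Q)
    status[truth > 0] <- "experimental"
    status
  }

  tr <- draw_cluster_samples(cfg$n_train, centers, cfg)
  te <- draw_cluster_samples(cfg$n_test, centers, cfg)
  po <- draw_cluster_samples(cfg$n_pool, centers, cfg)

  pool_status <- matrix("negative", cfg$n_pool, Q)
  pool_correct <- logical(cfg$n_pool)
  for (i in seq_len(cfg$n_pool)) {
    true_pos <- which(po$truth[i, ] > 0)
    shown <- integer(0)
    ok <- TRUE
    for (l in true_pos) {
      ev <- sample(nonexp_types(), 1L, prob = cfg$evidence_mix)
      target <- l
      if (runif(1L) < cfg$corruption[[ev]]) {
        free <- setdiff(seq_len(Q), c(true_pos, shown))
        if (length(free) > 0L) {
          target <- if (length(free) == 1L) free else sample(free, 1L)
          ok <- FALSE
        }
      }
      if (pool_status[i, target] == "negative") {
        pool_status[i, target] <- ev
        shown <- c(shown, target)
      }
    }
    pool_correct[i] <- ok
  }

  mk <- function(feats, status, prefix) {
    labeled_set(feats, status, locations = locations,
                ids = sprintf("%s%04d", prefix, seq_len(nrow(feats))))
  }
  structure(list(
    train = mk(tr$features, sign_to_status(tr$truth), "TR"),
    pool = mk(po$features, pool_status, "PO"),
    test = mk(te$features, sign_to_status(te$truth), "TE"),
    truth_pool = po$truth, truth_test = te$truth,
    pool_correct = pool_correct,
    config = cfg), class = "pneaselect_synthetic_study")
}

#' Fraction of a selection whose non-experimental labels are all correct
#'
#' @param selection_ids character vector of selected pool ids.
#' @param study a `pneaselect_synthetic_study`.
#' @return fraction in `[0, 1]`.
#' @export
enrichment_score <- function(selection_ids, study) {
  if (length(selection_ids) == 0L) stop("empty selection")
  idx <- match(selection_ids, study$pool$ids)
  if (anyNA(idx)) stop("selection ids outside the pool")
  mean(study$pool_correct[idx])
}
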