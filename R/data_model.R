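#' Clustered individual-participant dataset
#'
#' Wraps a flat participant-level table (one row per individual) with a
#' cluster identifier and a binary outcome, the basic container for
#' internal-external cross-validation. Clusters may be studies, centers,
#' regions or any other grouping within which participants were collected
#' under shared conditions.
#'
#' Cluster labels keep their order of first appearance in the input; every
#' loop over clusters in this package iterates in that order, so results are
#' reproducible from the file alone.
#'
#' @param data data.frame with one row per participant.
#' @param cluster_col name of the cluster identifier column.
#' @param outcome_col name of the binary (0/1) outcome column.
#' @return An object of class `clustered_dataset`: a list with elements
#'   `data` (the validated data.frame), `cluster_col`, `outcome_col`,
#'   `clusters` (labels in first-appearance order), `n_k` (named per-cluster
#'   row counts) and `N`.
#' @details Missing values anywhere are an error: imputation must be done
#'   upstream. Predictor columns must be numeric (binary variables coded
#'   0/1). At least two clusters are required, each with at least one row;
#'   the stricter requirement that a cluster holds both an event and a
#'   non-event is checked at model-fitting time, not here, because clusters
#'   may legitimately be validation-only.
#' @seealso [load_dataset()] to read from a delimited file,
#'   [build_design()] to expand model terms into a design matrix.
#' @export
clustered_dataset <- function(data, cluster_col, outcome_col) {
  if (!is.data.frame(data)) stop_validation("`data` must be a data.frame")
  for (col in c(cluster_col, outcome_col)) {
    if (!col %in% names(data)) {
      stop_config("column '", col, "' not found in data")
    }
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  y <- data[[outcome_col]]
  if (anyNA(data)) {
    bad <- names(data)[vapply(data, anyNA, logical(1))]
    stop_validation("missing values in column(s): ", paste(bad, collapse = ", "))
  }
  if (!all(y %in% c(0, 1))) {
    stop_validation("outcome column '", outcome_col, "' must contain only 0 and 1")
  }
  cl <- as.character(data[[cluster_col]])
  clusters <- unique(cl)
  if (length(clusters) < 2) {
    stop_validation("at least 2 clusters are required, found ", length(clusters))
  }
  pred_cols <- setdiff(names(data), c(cluster_col, outcome_col))
  non_num <- pred_cols[!vapply(data[pred_cols], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    stop_validation("predictor column(s) not numeric: ", paste(non_num, collapse = ", "))
  }
  n_k <- vapply(clusters, function(k) sum(cl == k), integer(1))
  structure(
    list(
      data = data,
      cluster_col = cluster_col,
      outcome_col = outcome_col,
      clusters = clusters,
      n_k = n_k,
      N = nrow(data)
    ),
    class = "clustered_dataset"
  )
}

#' @export
print.clustered_dataset <- function(x, ...) {
  cat("Clustered dataset:", x$N, "participants in", length(x$clusters), "clusters\n")
  cat("  outcome:", x$outcome_col,
      sprintf("(%d events, %.1f%%)", sum(outcome(x)), 100 * mean(outcome(x))), "\n")
  cat("  cluster sizes:", paste(x$n_k, collapse = ", "), "\n")
  invisible(x)
}

# Row labels / outcome accessors used throughout the engine.
cluster_labels <- function(x) as.character(x$data[[x$cluster_col]])

outcome <- function(x) as.numeric(x$data[[x$outcome_col]])

#' Subset a clustered dataset by cluster
#'
#' @param x a `clustered_dataset`.
#' @param keep character vector of cluster labels to keep (order of first
#'   appearance is preserved from the original dataset).
#' @return A `clustered_dataset` restricted to the named clusters.
#' @export
subset_clusters <- function(x, keep) {
  stopifnot(inherits(x, "clustered_dataset"))
  missing <- setdiff(keep, x$clusters)
  if (length(missing) > 0) {
    stop_validation("unknown cluster(s): ", paste(missing, collapse = ", "))
  }
  rows <- cluster_labels(x) %in% keep
  clustered_dataset(x$data[rows, , drop = FALSE], x$cluster_col, x$outcome_col)
}

#' Read a clustered dataset from a delimited text file
#'
#' @param path path to a CSV (default) or TSV file with a header row.
#' @param cluster_col,outcome_col column names, as in [clustered_dataset()].
#' @param sep field delimiter, `","` or `"\t"`.
#' @return A validated `clustered_dataset`.
#' @export
load_dataset <- function(path, cluster_col, outcome_col, sep = ",") {
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  clustered_dataset(df, cluster_col, outcome_col)
}

#' Write a clustered dataset to a delimited text file
#'
#' Inverse of [load_dataset()]: a write/reload round-trip preserves values
#' and cluster order.
#'
#' @param x a `clustered_dataset`.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_dataset <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "clustered_dataset"))
  utils::write.table(x$data, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Model terms
#'
#' A term describes one column of the design matrix as a deterministic
#' function of the base predictor columns (or of other named terms).
#' Supported transforms:
#' \describe{
#'   \item{identity}{the source column unchanged.}
#'   \item{scale}{the source divided by a constant (e.g. age/25, chosen to
#'     put coefficients on a convenient scale).}
#'   \item{log}{natural log; requires strictly positive values.}
#'   \item{square_centered}{the source is centered on its within-cluster
#'     mean, then squared. Centering means are computed from the data the
#'     design is built on, so a hold-out cluster is centered with its own
#'     means — a deployed model cannot know development-cluster means for
#'     a new cluster.}
#' }
#' An interaction term multiplies two or more sources elementwise; a source
#' may be a base column or the name of another term in the same model
#' specification (so e.g. `age25 x malignancy` reuses the scaled term).
#'
#' @param name unique term name.
#' @param source base column (or term) name; for `term_interaction` a
#'   character vector of two or more.
#' @param by positive scaling constant for `term_scale`.
#' @return An object of class `siecv_term`.
#' @export
term_main <- function(name, source = name) {
  new_term(name, "main", source, "identity", NULL)
}

#' @rdname term_main
#' @export
term_scale <- function(name, source, by) {
  stopifnot(is.numeric(by), length(by) == 1, is.finite(by), by != 0)
  new_term(name, "transform", source, "scale", by)
}

#' @rdname term_main
#' @export
term_log <- function(name, source) {
  new_term(name, "transform", source, "log", NULL)
}

#' @rdname term_main
#' @export
term_square_centered <- function(name, source) {
  new_term(name, "transform", source, "square_centered", NULL)
}

#' @rdname term_main
#' @export
term_interaction <- function(name, source) {
  if (length(source) < 2) {
    stop_validation("an interaction term needs at least 2 source variables")
  }
  new_term(name, "interaction", source, "product", NULL)
}

new_term <- function(name, kind, source, transform, by) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (kind != "interaction" && length(source) != 1) {
    stop_validation("term '", name, "': a ", kind, " term references exactly 1 source")
  }
  structure(
    list(name = name, kind = kind, source = source, transform = transform, by = by),
    class = "siecv_term"
  )
}

#' @export
print.siecv_term <- function(x, ...) {
  desc <- switch(x$transform,
    identity = x$source,
    scale = paste0(x$source, "/", x$by),
    log = paste0("log(", x$source, ")"),
    square_centered = paste0("(", x$source, " - cluster mean)^2"),
    product = paste(x$source, collapse = " * ")
  )
  cat("<term>", x$name, "=", desc, "\n")
  invisible(x)
}

#' Model specification
#'
#' Holds the terms currently in the model (always implicitly including an
#' intercept), the subset that is forced (never removable), and the ordered
#' set of candidate terms not yet included. The candidate order is the
#' deterministic tie-break used by the stepwise engine.
#'
#' @param included list of [term_main()]-style terms currently in the model
#'   (may be empty for an intercept-only model).
#' @param candidates list of candidate terms not yet included.
#' @param forced character vector of names of included terms that may never
#'   be removed.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(included = list(), candidates = list(), forced = character()) {
  included <- as_term_list(included)
  candidates <- as_term_list(candidates)
  inc_names <- vapply(included, `[[`, character(1), "name")
  cand_names <- vapply(candidates, `[[`, character(1), "name")
  all_names <- c(inc_names, cand_names)
  if (anyDuplicated(all_names)) {
    stop_validation("duplicate term names: ",
                    paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  }
  if (length(intersect(inc_names, cand_names)) > 0) {
    stop_validation("included and candidate sets must be disjoint")
  }
  if (!all(forced %in% inc_names)) {
    stop_validation("forced terms must be included: ",
                    paste(setdiff(forced, inc_names), collapse = ", "))
  }
  structure(
    list(included = included, candidates = candidates, forced = forced),
    class = "model_spec"
  )
}

as_term_list <- function(x) {
  if (inherits(x, "siecv_term")) x <- list(x)
  stopifnot(is.list(x))
  lapply(x, function(t) {
    if (!inherits(t, "siecv_term")) stop_validation("terms must be built with term_*()")
    t
  })
}

term_names <- function(terms) vapply(terms, `[[`, character(1), "name")

#' @export
print.model_spec <- function(x, ...) {
  inc <- term_names(x$included)
  cat("Model: intercept",
      if (length(inc)) paste("+", paste(inc, collapse = " + ")) else "(only)", "\n")
  if (length(x$forced)) cat("  forced:", paste(x$forced, collapse = ", "), "\n")
  if (length(x$candidates)) {
    cat("  candidates:", paste(term_names(x$candidates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build the design matrix for a set of terms
#'
#' Expands the included terms of a model specification into a numeric
#' matrix with an intercept column followed by one column per term, in
#' order. The expansion is a pure function of the input data: within-cluster
#' centering statistics (for `square_centered` terms) are recomputed from
#' the clusters present in `data`.
#'
#' @param data a `clustered_dataset`.
#' @param spec a `model_spec`, or a plain list of terms.
#' @return Numeric matrix with `data$N` rows; first column `(Intercept)`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(data, "clustered_dataset"))
  terms <- if (inherits(spec, "model_spec")) spec$included else as_term_list(spec)
  nms <- term_names(terms)
  cl <- cluster_labels(data)
  cols <- new.env(parent = emptyenv())
  resolving <- character()

  resolve <- function(src, self = NULL) {
    # a source is either another term in the spec or a base column; a term
    # whose source carries its own name (a plain main effect) reads the
    # base column, not itself
    if (!identical(src, self) && !is.null(cols[[src]])) return(cols[[src]])
    idx <- if (identical(src, self)) NA_integer_ else match(src, nms)
    if (!is.na(idx)) {
      if (src %in% resolving) stop_validation("circular term definition at '", src, "'")
      resolving <<- c(resolving, src)
      v <- compute(terms[[idx]])
      resolving <<- setdiff(resolving, src)
      cols[[src]] <- v
      return(v)
    }
    if (!src %in% names(data$data)) {
      stop_validation("term source '", src, "' not found in data")
    }
    as.numeric(data$data[[src]])
  }

  compute <- function(t) {
    if (t$kind == "interaction") {
      return(Reduce(`*`, lapply(t$source, resolve, self = t$name)))
    }
    x <- resolve(t$source, self = t$name)
    switch(t$transform,
      identity = x,
      scale = x / t$by,
      log = {
        if (any(x <= 0)) {
          stop_validation("term '", t$name, "': log of non-positive value in '",
                          t$source, "'")
        }
        log(x)
      },
      square_centered = {
        ctr <- stats::ave(x, cl)
        (x - ctr)^2
      }
    )
  }

  X <- cbind(`(Intercept)` = rep(1, data$N))
  for (t in terms) X <- cbind(X, compute(t))
  colnames(X) <- c("(Intercept)", nms)
  X
}

#' Serialize / deserialize a model specification
#'
#' Converts between a `model_spec` and the plain-list layout used in YAML
#' or JSON run configurations: each term is a list with fields `name`,
#' `kind`, `source`, `transform` and (for scale transforms) `by`.
#'
#' @param spec a `model_spec`.
#' @return `spec_to_list()`: a list with `included`, `candidates`, `forced`.
#' @export
spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  dump1 <- function(t) {
    out <- list(name = t$name, kind = t$kind, source = t$source,
                transform = t$transform)
    if (!is.null(t$by)) out$by <- t$by
    out
  }
  list(
    included = lapply(spec$included, dump1),
    candidates = lapply(spec$candidates, dump1),
    forced = as.list(spec$forced)
  )
}

#' @rdname spec_to_list
#' @param x plain list as produced by [spec_to_list()] or parsed from a
#'   YAML/JSON configuration.
#' @export
spec_from_list <- function(x) {
  load1 <- function(t) {
    if (is.null(t$name)) stop_config("term descriptor without a 'name'")
    transform <- if (is.null(t$transform)) "identity" else t$transform
    kind <- if (is.null(t$kind)) {
      if (transform == "product") "interaction"
      else if (transform == "identity") "main" else "transform"
    } else t$kind
    src <- unlist(t$source)
    if (is.null(src)) src <- t$name
    switch(kind,
      main = term_main(t$name, src),
      transform = switch(transform,
        scale = term_scale(t$name, src, t$by),
        log = term_log(t$name, src),
        square_centered = term_square_centered(t$name, src),
        stop_config("unknown transform '", transform, "' for term '", t$name, "'")
      ),
      interaction = term_interaction(t$name, src),
      stop_config("unknown term kind '", kind, "' for term '", t$name, "'")
    )
  }
  model_spec(
    included = lapply(x$included, load1),
    candidates = lapply(x$candidates, load1),
    forced = as.character(unlist(x$forced))
  )
}
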