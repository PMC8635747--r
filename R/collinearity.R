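#' Pearson correlation matrix of an environmental matrix
#'
#' Product-moment correlations over the complete-case rows of the
#' environmental matrix. A zero-variance column is a hard error (it has no
#' defined correlation and would poison the screen).
#'
#' @param env an `"env_matrix"` (see [build_env_matrix()]), or a plain
#'   numeric data.frame/matrix of variables.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(env) {
  X <- env_values(env)
  if (nrow(X) < 3) stop_ecogeo("need at least 3 complete rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop_ecogeo("zero-variance column: ",
                paste(colnames(X)[sds == 0 | is.na(sds)], collapse = ", "))
  stats::cor(X)
}

# pull the numeric variable block out of the containers used in the pipeline
env_values <- function(env) {
  if (inherits(env, "env_matrix")) env <- env$env
  if (is.data.frame(env))
    env <- env[, !(names(env) %in% c("record_id", "species")), drop = FALSE]
  X <- as.matrix(env)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' Screen variables for collinearity
#'
#' Greedy elimination of collinear variables: while any retained pair has
#' `|r| > threshold`, the pair with the largest `|r|` is taken and one
#' member is eliminated. Under the default rule the member *conserved* is
#' the one with the greater number of `|r| > threshold` partners among the
#' currently retained variables (the "hub", which replaces the most
#' information); ties go to the larger sum of `|r|` against retained
#' variables, then to input column order. Every step is logged so the
#' procedure is auditable, and `rule = "drop_hub"` swaps the retention
#' choice for sensitivity analysis.
#'
#' @param mat symmetric correlation matrix with named rows/columns (e.g.,
#'   from [pearson_matrix()]).
#' @param threshold absolute-correlation cutoff, default 0.90.
#' @param rule `"conserve_hub"` (default) or `"drop_hub"`.
#' @return object of class `"collinearity_screen"`: `retained`,
#'   `eliminated`, `threshold`, `rule`, the input `matrix`, and `log`
#'   (data.frame: step, var_a, var_b, r, n_high_a, n_high_b, conserved,
#'   eliminated, tie_count, tie_sum).
#' @export
screen_collinear <- function(mat, threshold = 0.90,
                             rule = c("conserve_hub", "drop_hub")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (is.null(colnames(mat))) stop_ecogeo("correlation matrix must be named")
  vars <- colnames(mat)
  retained <- vars
  log <- list()
  step <- 0L
  repeat {
    A <- abs(mat[retained, retained, drop = FALSE])
    diag(A) <- 0
    mx <- max(A)
    if (mx <= threshold || length(retained) < 2) break
    step <- step + 1L
    # pair with largest |r|; ties resolved by input column order (a, then b)
    hits <- which(A == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    a <- retained[i]; b <- retained[j]
    n_high <- function(k) sum(A[k, ] > threshold)
    na <- n_high(i); nb <- n_high(j)
    tie_count <- na == nb
    tie_sum <- FALSE
    if (!tie_count) {
      keep <- if (na > nb) a else b
    } else {
      sa <- sum(A[i, ]); sb <- sum(A[j, ])
      if (sa != sb) {
        keep <- if (sa > sb) a else b
      } else {
        tie_sum <- TRUE
        keep <- a  # earlier input column order
      }
    }
    if (rule == "drop_hub") keep <- if (keep == a) b else a
    drop <- if (keep == a) b else a
    log[[step]] <- data.frame(step = step, var_a = a, var_b = b,
                              r = mat[a, b], n_high_a = na, n_high_b = nb,
                              conserved = keep, eliminated = drop,
                              tie_count = tie_count, tie_sum = tie_sum,
                              stringsAsFactors = FALSE)
    retained <- setdiff(retained, drop)
  }
  structure(list(retained = retained,
                 eliminated = setdiff(vars, retained),
                 threshold = threshold, rule = rule, matrix = mat,
                 log = if (length(log)) do.call(rbind, log) else
                   data.frame(step = integer(), var_a = character(),
                              var_b = character(), r = numeric(),
                              n_high_a = integer(), n_high_b = integer(),
                              conserved = character(),
                              eliminated = character(),
                              tie_count = logical(), tie_sum = logical())),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("Collinearity screen (|r| > %g, %s): %d retained, %d eliminated\n",
              x$threshold, x$rule, length(x$retained), length(x$eliminated)))
  if (length(x$eliminated))
    cat("  eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  invisible(x)
}
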