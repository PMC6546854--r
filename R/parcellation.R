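#' Construct a parcellation object
#'
#' A parcellation couples a 3D integer label volume (0 = outside the analysis
#' mask) with an ordered region table. The analysis mask is exactly the set of
#' voxels carrying a nonzero label.
#'
#' @param labels 3D integer array; 0 marks voxels outside the mask.
#' @param region_table data frame with columns `label` and `name`, one row per
#'   region, ordered as the downstream region vectors will be.
#' @return An object of class `parcellation` with elements `labels`,
#'   `region_table` and `mask`.
#' @export
parcellation <- function(labels, region_table = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  labs <- sort(unique(as.integer(labels[labels > 0])))
  if (length(labs) == 0) stop("parcellation has no labelled voxels")
  if (is.null(region_table)) {
    region_table <- data.frame(label = labs, name = sprintf("R%03d", labs),
                               stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "name") %in% names(region_table)))
  if (!identical(sort(as.integer(region_table$label)), labs))
    stop("region_table labels do not match the labels present in the volume")
  structure(list(labels = labels,
                 region_table = region_table,
                 mask = labels > 0),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("parcellation: %d x %d x %d grid, %d regions, %d masked voxels\n",
              d[1], d[2], d[3], nrow(x$region_table), sum(x$mask)))
  invisible(x)
}

#' Build a block parcellation for synthetic experiments
#'
#' Partitions a rectangular grid into `n_regions` contiguous rectangular
#' blocks, each at least 3 voxels along every axis so that every region can
#' host a full 3x3x3 neighbourhood. The mask covers the whole grid. This is a
#' deliberately simple stand-in for an anatomical atlas: region geometry is
#' not the object of study here, only the aggregation of voxel maps into
#' region vectors.
#'
#' @param grid_shape integer vector of length 3.
#' @param n_regions number of regions.
#' @param seed kept for interface symmetry with the other generators; the
#'   construction is deterministic.
#' @param region_names optional character vector of region names (defaults to
#'   `R001`, `R002`, ...).
#' @return A [parcellation] object.
#' @export
make_toy_parcellation <- function(grid_shape, n_regions, seed = 1L,
                                  region_names = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), n_regions >= 1)
  if (prod(grid_shape) < 27 * n_regions)
    stop(sprintf("grid too small: %d voxels cannot host %d regions of >= 27 voxels",
                 prod(grid_shape), n_regions))

  # factor n_regions into axis split counts with >= 3 voxels per block side
  divs <- Filter(function(k) n_regions %% k == 0, seq_len(n_regions))
  best <- NULL
  for (f1 in divs) for (f2 in Filter(function(k) (n_regions / f1) %% k == 0, divs)) {
    f3 <- n_regions / (f1 * f2)
    f <- c(f1, f2, f3)
    sides <- floor(grid_shape / f)
    if (any(sides < 3)) next
    score <- c(min(sides), -stats::var(f))
    if (is.null(best) || score[1] > best$score[1] ||
        (score[1] == best$score[1] && score[2] > best$score[2])) {
      best <- list(f = f, score = score)
    }
  }
  if (is.null(best))
    stop(sprintf("grid too small: no axis split of %s supports %d blocks with sides >= 3",
                 paste(grid_shape, collapse = "x"), n_regions))
  f <- best$f

  block_index <- function(n, parts) {
    cuts <- floor(seq(0, n, length.out = parts + 1))
    findInterval(seq_len(n) - 1L, cuts, rightmost.closed = TRUE)
  }
  b1 <- block_index(grid_shape[1], f[1])
  b2 <- block_index(grid_shape[2], f[2])
  b3 <- block_index(grid_shape[3], f[3])
  lab <- outer(outer(b1, (b2 - 1L) * f[1], `+`), (b3 - 1L) * f[1] * f[2], `+`)
  labels <- array(as.integer(lab), dim = grid_shape)

  tab <- data.frame(label = seq_len(n_regions),
                    name = region_names %||% sprintf("R%03d", seq_len(n_regions)),
                    stringsAsFactors = FALSE)
  parcellation(labels, tab)
}

#' The 90-region anatomical atlas table
#'
#' Ordered label/name table of the 90 cortical and subcortical regions
#' (45 per hemisphere, cerebellum excluded) of the Automated Anatomical
#' Labeling atlas, in the ordering used by the region vectors of this
#' package's study preset.
#'
#' @return data frame with columns `label` and `name` (90 rows).
#' @export
aal_region_table <- function() {
  path <- system.file("extdata", "aal90_regions.tsv", package = "rsmvpa")
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  tab$label <- as.integer(tab$label)
  tab
}
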