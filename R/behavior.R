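#' Score the delayed face-placement memory test
#'
#' Faces are placed on an 18-cell grid (3 rows x 6 columns; cell ids 1-18
#' in row-major order). Per face the rubric is exclusive and hierarchical:
#' 3 points for the exact cell, else 1 point for the correct column, else
#' 0.5 for the correct row, else 0. (On a grid, correct column *and*
#' correct row implies the exact cell, so the hierarchy is unambiguous.)
#'
#' @param truth,placement integer vectors of length 18 mapping each face to
#'   a cell id; each must use every cell exactly once.
#' @return total score in `[0, 54]`.
#' @export
#' @examples
#' face_memory_score(1:18, 1:18) # 54
face_memory_score <- function(truth, placement) {
  check_grid <- function(x, what) {
    if (length(x) != 18L || !all(sort(as.integer(x)) == 1:18))
      stop(what, " must assign all 18 faces to distinct cells 1-18")
    as.integer(x)
  }
  truth <- check_grid(truth, "truth")
  placement <- check_grid(placement, "placement")
  row_of <- function(cell) (cell - 1L) %/% 6L
  col_of <- function(cell) (cell - 1L) %% 6L
  pts <- ifelse(placement == truth, 3,
           ifelse(col_of(placement) == col_of(truth), 1,
             ifelse(row_of(placement) == row_of(truth), 0.5, 0)))
  sum(pts)
}

#' Shortest map distance from a maze position to the goal
#'
#' Graph shortest-path length from the position reached after the allotted
#' search time to the goal node (breadth-first on unit edges, Dijkstra
#' otherwise, via igraph). Smaller is better.
#'
#' @param graph igraph graph; the goal is its `goal` graph attribute unless
#'   given.
#' @param position node id.
#' @param goal optional goal node override.
#' @return list with `distance` (numeric; `Inf` when unreachable) and
#'   `reachable` (logical flag — check it before using the number).
#' @export
maze_memory_distance <- function(graph, position, goal = NULL) {
  if (is.null(goal)) goal <- igraph::graph_attr(graph, "goal")
  if (is.null(goal)) stop("no goal node defined")
  nv <- igraph::vcount(graph)
  if (!position %in% seq_len(nv)) stop("position not a node of the graph")
  d <- igraph::distances(graph, v = position, to = goal)[1L, 1L]
  list(distance = unname(d), reachable = is.finite(d))
}

#' Cohort z-scores of memory performance
#'
#' Standardizes face scores and maze distances across the cohort so the two
#' tasks are comparable; maze distances are negated first, so a larger
#' z-score always indexes better memory.
#'
#' @param face_scores,maze_distances numeric vectors, one value per subject.
#' @return data.frame with `face_z`, `maze_z`.
#' @export
zscore_memory <- function(face_scores, maze_distances) {
  stopifnot(length(face_scores) == length(maze_distances),
            length(face_scores) >= 3L)
  if (sd(face_scores) == 0 || sd(maze_distances) == 0)
    stop("zero variance in memory scores; z-scores undefined")
  data.frame(face_z = as.numeric(scale(face_scores)),
             maze_z = as.numeric(scale(-maze_distances)))
}

#' Correlate reactivation strength with memory performance
#'
#' Spearman correlation (two-sided) between a per-subject reactivation
#' measure (e.g. mean reactivation-network beta during N3) and memory
#' z-scores.
#'
#' @param strength,memory_z numeric vectors, length >= 5.
#' @return list `rho`, `p`, `n`, `defined` (FALSE when an input is
#'   constant).
#' @export
reactivation_memory_correlation <- function(strength, memory_z) {
  stopifnot(length(strength) == length(memory_z), length(strength) >= 5L)
  if (sd(strength) == 0 || sd(memory_z) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(strength),
                defined = FALSE))
  r <- spearman_cor(strength, memory_z)
  list(rho = r$rho, p = r$p, n = length(strength), defined = TRUE)
}
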