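#' The 26-voxel neighborhood and its 13 canonical half offsets
#'
#' Each voxel has 26 adjacent voxels (all displacement components in
#' \{-1, 0, 1\}, excluding the null displacement). Correlation templates
#' store only 13 maps because the correlation with the neighbor at offset
#' `-o` is the correlation with offset `o` evaluated at the displaced voxel;
#' the canonical half keeps, of each pair \{o, -o\}, the offset that is
#' lexicographically positive in (dz, dy, dx) order.
#'
#' Offsets are returned in a fixed documented order: lexicographic in
#' (dz, dy, dx) from (-1,-1,-1) to (1,1,1), skipping (0,0,0). Under this
#' order the last 13 offsets are exactly the canonical half and the first
#' 13 are their negations in reverse order.
#'
#' @return A list of class `neighbor_offsets` with
#'   \describe{
#'     \item{offsets}{26 x 3 integer matrix, columns (dx, dy, dz).}
#'     \item{unique_half}{13 x 3 integer matrix, the canonical
#'       representatives.}
#'     \item{half_index}{length-26 integer: for each offset, the row of
#'       `unique_half` storing its correlation.}
#'     \item{is_half}{length-26 logical: whether the offset itself is the
#'       stored representative (otherwise the value lives at the displaced
#'       voxel under the negated offset).}
#'   }
#' @examples
#' no <- neighbor_offsets()
#' nrow(no$offsets)      # 26
#' nrow(no$unique_half)  # 13
#' @export
neighbor_offsets <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[order(g$dz, g$dy, g$dx), ]
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  offsets <- as.matrix(g)
  dimnames(offsets) <- list(NULL, c("dx", "dy", "dz"))
  storage.mode(offsets) <- "integer"
  is_half <- offsets[, "dz"] > 0L |
    (offsets[, "dz"] == 0L & offsets[, "dy"] > 0L) |
    (offsets[, "dz"] == 0L & offsets[, "dy"] == 0L & offsets[, "dx"] > 0L)
  unique_half <- offsets[is_half, , drop = FALSE]
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  half_key <- key(unique_half)
  half_index <- integer(26)
  half_index[is_half] <- match(key(offsets[is_half, , drop = FALSE]),
                               half_key)
  half_index[!is_half] <- match(key(-offsets[!is_half, , drop = FALSE]),
                                half_key)
  structure(list(offsets = offsets, unique_half = unique_half,
                 half_index = half_index, is_half = is_half),
            class = "neighbor_offsets")
}
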