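# Internal helpers shared across modules.

tj_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(paste0("tjquant_error_", class), "tjquant_error"), ...)
}

#' Derive a reproducible child seed from a master seed
#'
#' Child seeds are a stable polynomial hash of the master seed together with
#' a module name and an item identifier, so adding images to a run never
#' perturbs the seeds of existing ones. All arithmetic is exact in doubles.
#'
#' @param master_seed Integer master seed of the run.
#' @param module Character scalar naming the operation (e.g. "simulate").
#' @param id Character or integer identifier of the item (e.g. an image id).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate", "control_01")
derive_seed <- function(master_seed, module, id) {
  key <- paste(master_seed, module, id, sep = "/")
  bytes <- utf8ToInt(key)
  p <- 2^31 - 1  # Mersenne prime modulus; 127 * p + 255 < 2^53, so exact
  h <- 17
  for (b in bytes) h <- (h * 127 + b) %% p
  as.integer(h %% (2^31 - 2)) + 1L
}

# result[i, j] = m[i + dr, j + dc], out-of-range filled with `fill`
shift_mat <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 - dr):min(h, h - dr)
  cs <- max(1, 1 - dc):min(w, w - dc)
  if (length(rs) > 0 && length(cs) > 0) out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# sum of every k x k window; result is (h-k+1) x (w-k+1)
window_sums <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(k <= h, k <= w)
  S <- rbind(0, apply(m, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  rs <- 1:(h - k + 1); cs <- 1:(w - k + 1)
  S[rs + k, cs + k, drop = FALSE] - S[rs, cs + k, drop = FALSE] -
    S[rs + k, cs, drop = FALSE] + S[rs, cs, drop = FALSE]
}

# connected-component labeling of a logical matrix; 4- or 8-connectivity
label_components <- function(m, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  fg <- which(m)
  if (length(fg) == 0L) return(lab)
  vmap <- integer(h * w)
  vmap[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  li <- matrix(seq_len(h * w), h, w)
  edges <- integer(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    rs <- max(1, 1 - dr):min(h, h - dr)
    cs <- max(1, 1 - dc):min(w, w - dc)
    a <- m[rs, cs, drop = FALSE] & m[rs + dr, cs + dc, drop = FALSE]
    if (any(a)) {
      src <- li[rs, cs, drop = FALSE][a]
      dst <- li[rs + dr, cs + dc, drop = FALSE][a]
      edges <- c(edges, rbind(vmap[src], vmap[dst]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber components in raster order of their first pixel, for determinism
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[fg] <- relab[memb]
  lab
}

# binary dilation by a disc of the given radius (pixels); radius 0 is identity
dilate_disc <- function(m, radius) {
  if (radius <= 0) return(m)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  as.matrix(EBImage::dilate(m * 1, brush)) > 0
}

sig_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}
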