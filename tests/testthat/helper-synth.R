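# Shared fixtures: small synthetic scenes built in code.

## Compact noiseless scene for round-trip tests.
tiny_scene <- function(n_mito = 20, seed = 11, image_shape = c(96L, 96L), ...) {
  build_scene(scene_config(image_shape = image_shape, n_mito = n_mito,
                           seed = seed, motility_amplitude = 0, ...))
}

## Match detected ROI centroids to truth centers; returns index of the
## nearest truth object per ROI and the distances.
match_rois <- function(rois, scene) {
  m <- scene$mitochondria
  d2 <- outer(rois$centroids$y, m$y, "-")^2 + outer(rois$centroids$x, m$x, "-")^2
  nearest <- apply(d2, 1, which.min)
  list(nearest = nearest,
       dist = sqrt(d2[cbind(seq_along(nearest), nearest)]))
}

## Precision/recall of a detection against truth at a matching radius.
detection_scores <- function(rois, scene, radius = 2) {
  mt <- match_rois(rois, scene)
  hit <- mt$dist <= radius
  matched_truth <- unique(mt$nearest[hit])
  list(recall = length(matched_truth) / nrow(scene$mitochondria),
       precision = if (nrow(rois$centroids)) sum(hit) / nrow(rois$centroids) else 0)
}
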