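# Builders and independent oracles shared across test files.

# A clip from a list of H x W x 3 arrays (values 0..255).
make_clip <- function(frames, onset = 0, apex = NA, offset = length(frames) - 1,
                      subject = "s01", id = "c01", label = "negative") {
  microres:::new_clip(
    clip_annotation(subject, id, onset, apex, offset, label), frames)
}

# A random 8-bit clip of n_frames frames of h x w.
random_clip <- function(n_frames, h = 8, w = 8) {
  make_clip(lapply(seq_len(n_frames), function(i)
    array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)), c(h, w, 3))))
}

# Key-frame set literal (bypassing selection) for residual tests.
kf_literal <- function(start, frames) {
  structure(list(start = as.integer(start), end = max(frames),
                 gap = 1L, n_key = length(frames),
                 frames = as.integer(frames)),
            class = "keyframe_set")
}

# Independent per-pixel loop oracles for the residual images.
oracle_diff <- function(clip, kf) {
  ref <- clip$frames[[kf$start + 1L]]
  d <- dim(ref)
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    s <- 0
    for (f in kf$frames) s <- s + abs(clip$frames[[f + 1L]][x, y, z] - ref[x, y, z])
    out[x, y, z] <- s
  }
  out
}

oracle_ars <- function(clip, kf) oracle_diff(clip, kf) %% 256

oracle_rrs <- function(clip, kf, gmin = 0, gmax = 255) {
  d <- oracle_diff(clip, kf)
  lo <- min(d); hi <- max(d)
  if (hi == lo) return(array(gmin, dim(d)))
  round((d - lo) / (hi - lo) * (gmax - gmin) + gmin)
}

# Small configurations for fast model tests.
test_backbone <- function() {
  backbone_spec(channel_schedule = c(6, 12), feature_dim = 8,
                input_downsample = 2, head_channels = 16)
}

test_cgpo <- function(size = 64) {
  cgpo_config(input_size = size, tile_size = size %/% 2L, alpha = 0.3)
}
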