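# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# Desk-scale phantom: realistic head radii on a 2 mm grid.
desk_spec <- function(noise = TRUE, seed = 1L) {
  phantom_spec(grid_shape = c(98, 118, 110), voxel_spacing_mm = 2,
               noise_sd = if (noise) list(ct = 20, zte = 0.015, t1w = 0.03)
               else list(ct = 0, zte = 0, t1w = 0),
               seed = seed)
}

clean_phantom <- function() memo("clean_phantom", generate_phantom(desk_spec(noise = FALSE)))
noisy_phantom <- function() memo("noisy_phantom", generate_phantom(desk_spec(noise = TRUE)))

# Small training-scale phantoms with 64x64 in-plane slices.
train_spec <- function(seed) {
  phantom_spec(grid_shape = c(64, 64, 56), voxel_spacing_mm = 3,
               head_radii_mm = c(52, 60, 50), seed = seed)
}

training_stacks <- function(modality = "zte", n_stacks = 200, n = 3) {
  key <- paste0("stacks_", modality, "_", n_stacks, "_", n)
  memo(key, {
    phs <- memo("train_phantoms", lapply(1:6, function(s) generate_phantom(train_spec(s))))
    st <- unlist(lapply(phs, function(p)
      make_slice_stacks(p[[modality]], p$head, p$ct, n = n)),
      recursive = FALSE)
    st <- st[vapply(st, function(s) sum(s$m) > 0, TRUE)]
    st[seq_len(n_stacks)]
  })
}

# A small bowl used for solver property tests (cheap domains).
small_bowl <- function() transducer_spec(roc_mm = 30,
                                         element_outer_diameters_mm = 28,
                                         kerf_mm = 0, frequency_hz = 500e3)

# Water-path free-field focus of the default annular array (shared fixture).
water_focus <- function() memo("water_focus", free_field_focus(transducer_spec()))
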