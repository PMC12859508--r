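# Example experiment configuration.
# Paths are resolved relative to this file's directory.
experiment_name: example
videos:
  - video1.ome.tif
  - video2.ome.tif
pixel_size: 0.1        # um per pixel; required when videos are plain .tif
temperature: 298       # K, enters kB*T
minimum_intensity: 0.3 # fraction of the frame maximum
min_size: 15           # approximate object diameter, px
max_size: 45
fill_threshold: 0.5    # fraction of the object's local peak
smoothing_width: 1.0   # keep close to 1.0
tracking_threshold: 15 # px
tracking_memory: 10    # frames
boundary_mode: condensate
min_frames: 200
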