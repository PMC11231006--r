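# Object / relation vocabulary for laparoscopic cholecystectomy streams.
# Colors are per-class constants (scene-graph node attributes), not pixel
# estimates; anatomies occur at most once per frame.
instruments: [grasper, bipolar, hook, scissors, clipper, irrigator]
anatomies: [gallbladder, liver, abdominal-wall-cavity, gut, omentum, cystic-duct, peritoneum]
verbs: [grasp, retract, dissect, coagulate, clip, cut, aspirate, irrigate]
colors:
  grasper: silver
  bipolar: blue
  hook: green
  scissors: gray
  clipper: purple
  irrigator: teal
  gallbladder: yellow
  liver: brown
  abdominal-wall-cavity: pink
  gut: red
  omentum: beige
  cystic-duct: white
  peritoneum: rose
phases: [preparation, calot-triangle-dissection, clipping-and-cutting,
         gallbladder-dissection, gallbladder-packaging,
         cleaning-and-coagulation, gallbladder-retraction]
grid_rows: [top, mid, bottom]
grid_cols: [left, mid, right]
relations: [left of, right of, above, below]
max_count: 6
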