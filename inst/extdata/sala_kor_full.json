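{
  "features": [
    {
      "kind": "HBA",
      "center": [2.77, 0, 0],
      "radius": 1.5,
      "label": "C1-HBA"
    },
    {
      "kind": "HBA",
      "center": [-0.335, 4.42209544923978, 0.25],
      "radius": 1.5,
      "label": "C2-HBA"
    },
    {
      "kind": "HBA",
      "center": [-3.59, -5.88735824365607, 0.2],
      "radius": 1.5,
      "label": "C4-HBA"
    },
    {
      "kind": "HY",
      "center": [-0.22, -0.381051177665153, 0],
      "radius": 1.5,
      "label": "HY-core"
    },
    {
      "kind": "HY",
      "center": [-2.395, 6.03209544923978, 0.68],
      "radius": 1.5,
      "label": "HY-acetoxy"
    },
    {
      "kind": "HY",
      "center": [-5.85152055598541, -3.7827395609876, 0.366666666666667],
      "radius": 1.5,
      "label": "HY-furan"
    }
  ],
  "exclusion_volumes": [
    {
      "center": [2.77, 0, 4.5],
      "radius": 1
    },
    {
      "center": [-0.335, 4.42209544923978, 4.5],
      "radius": 1
    },
    {
      "center": [-3.59, -5.88735824365607, 4.5],
      "radius": 1
    },
    {
      "center": [-0.22, -0.381051177665153, 4.5],
      "radius": 1
    },
    {
      "center": [-2.395, 6.03209544923978, 4.5],
      "radius": 1
    },
    {
      "center": [-5.85152055598541, -3.7827395609876, 4.5],
      "radius": 1
    },
    {
      "center": [2.77, 0, -4.5],
      "radius": 1
    },
    {
      "center": [-0.335, 4.42209544923978, -4.5],
      "radius": 1
    },
    {
      "center": [-3.59, -5.88735824365607, -4.5],
      "radius": 1
    },
    {
      "center": [-0.22, -0.381051177665153, -4.5],
      "radius": 1
    },
    {
      "center": [-2.395, 6.03209544923978, -4.5],
      "radius": 1
    },
    {
      "center": [-5.85152055598541, -3.7827395609876, -4.5],
      "radius": 1
    }
  ],
  "required_labels": [
    "C1-HBA",
    "C2-HBA",
    "C4-HBA",
    "HY-core",
    "HY-acetoxy",
    "HY-furan"
  ]
}
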