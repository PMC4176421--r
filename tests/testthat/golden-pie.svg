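<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="120" height="120" viewBox="0 0 120 120">
  <g id="nodes" fill="#F2F2F2" stroke="#666666" stroke-width="1">
    <ellipse cx="60" cy="60" rx="40" ry="40"/>
  </g>
  <g id="glyph-n1">
    <path d="M 60 60 L 60 20 A 40 40 0 0 1 100 60 Z" fill="#FF0000"/>
    <path d="M 60 60 L 100 60 A 40 40 0 0 1 60 100 Z" fill="#00FF00"/>
    <path d="M 60 60 L 60 100 A 40 40 0 0 1 60 20 Z" fill="#0000FF"/>
    <text x="74.1421" y="45.8579" text-anchor="middle" font-family="sans-serif" font-size="6.4" fill="#000000">a</text>
    <text x="74.1421" y="74.1421" text-anchor="middle" font-family="sans-serif" font-size="6.4" fill="#000000">b</text>
    <text x="40" y="60" text-anchor="middle" font-family="sans-serif" font-size="6.4" fill="#000000">c</text>
  </g>
</svg>
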