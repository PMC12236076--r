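<?xml version="1.0" encoding="UTF-8"?>
<annotation>
  <filename>example_scene.png</filename>
  <size>
    <width>640</width>
    <height>640</height>
    <depth>3</depth>
  </size>
  <object>
    <name>goosegrass</name>
    <bndbox>
      <xmin>221</xmin>
      <ymin>287</ymin>
      <xmax>395</xmax>
      <ymax>452</ymax>
    </bndbox>
  </object>
  <object>
    <name>beggartick</name>
    <bndbox>
      <xmin>193</xmin>
      <ymin>189</ymin>
      <xmax>367</xmax>
      <ymax>362</ymax>
    </bndbox>
  </object>
  <object>
    <name>goosegrass</name>
    <bndbox>
      <xmin>376</xmin>
      <ymin>197</ymin>
      <xmax>547</xmax>
      <ymax>347</ymax>
    </bndbox>
  </object>
</annotation>
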