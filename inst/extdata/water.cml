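<?xml version="1.0" encoding="UTF-8"?>
<molecule title="water">
  <atomArray>
    <atom id="a1" elementType="O" x3="0" y3="0" z3="0"/>
    <atom id="a2" elementType="H" x3="0.757" y3="0.586" z3="0"/>
    <atom id="a3" elementType="H" x3="-0.757" y3="0.586" z3="0"/>
  </atomArray>
  <bondArray>
    <bond atomRefs2="a1 a2" order="1"/>
    <bond atomRefs2="a1 a3" order="1"/>
  </bondArray>
</molecule>

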