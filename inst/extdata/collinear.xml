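<leaf name="collinear-wall-fixture">
  <nodes n="8">
    <node nr="0" x="0" y="0"/>
    <node nr="1" x="2" y="0"/>
    <node nr="2" x="2" y="1"/>
    <node nr="3" x="1" y="1"/>
    <node nr="4" x="0" y="1"/>
    <node nr="5" x="2" y="2"/>
    <node nr="6" x="1" y="2"/>
    <node nr="7" x="0" y="2"/>
  </nodes>
  <cells n="2">
    <cell index="0">
      <node n="0"/><node n="1"/><node n="2"/><node n="3"/><node n="4"/>
    </cell>
    <cell index="1">
      <node n="4"/><node n="3"/><node n="2"/><node n="5"/><node n="6"/><node n="7"/>
    </cell>
  </cells>
</leaf>
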